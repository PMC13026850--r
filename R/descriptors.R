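#' Deterministic scene descriptors from a mask
#'
#' Computes the per-scene summary quantities used for downstream text
#' summarization: per-class area ratios (which partition the image, so they
#' sum to 1), class presence flags, whether the instrument reaches the
#' image border (a cue that it extends beyond the field of view), and a
#' blur indicator. The blur indicator is the variance of the 4-neighbour
#' Laplacian response of the luma channel (the standard variance-of-
#' Laplacian focus measure, computed with the same frozen Laplacian kernel
#' and reflective borders the network stem uses); it is 0 for a constant
#' image and decreases when the image is blurred.
#'
#' Pure function: identical inputs give bit-identical descriptors.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param mask integer label mask of the same spatial size.
#' @param num_classes number of classes (default: `max(mask) + 1`, at
#'   least 2).
#' @param instrument_class label of the instrument class (default 1).
#' @param border_margin border band width in pixels for the touch test.
#' @return object of class `scene_descriptors`: list with `area_ratio`
#'   (per-class, sums to 1), `presence` (per-class logical),
#'   `instrument_border_touch`, `blur_score`, `image_size`.
#' @export
compute_descriptors <- function(image, mask, num_classes = NULL,
                                instrument_class = 1L, border_margin = 1L) {
  if (!identical(dim(image)[1:2], dim(mask))) {
    stopf("image and mask spatial sizes differ")
  }
  H <- nrow(mask); W <- ncol(mask)
  if (is.null(num_classes)) num_classes <- max(2L, max(as.integer(mask)) + 1L)
  cnt <- tabulate(as.integer(mask) + 1L, nbins = num_classes)
  area <- cnt / (H * W)
  frame <- matrix(FALSE, H, W)
  m <- border_margin
  frame[c(seq_len(m), H - seq_len(m) + 1L), ] <- TRUE
  frame[, c(seq_len(m), W - seq_len(m) + 1L)] <- TRUE
  touch <- any(mask[frame] == instrument_class)
  luma <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  bank <- make_frozen_bank()
  lap <- apply_frozen_bank(array(luma, dim = c(H, W, 1)), bank)[, , 3]
  structure(list(area_ratio = area,
                 presence = area > 0,
                 instrument_border_touch = touch,
                 blur_score = mean((lap - mean(lap))^2),
                 image_size = c(height = H, width = W),
                 instrument_class = as.integer(instrument_class)),
            class = "scene_descriptors")
}

#' Build a deterministic summarization prompt
#'
#' Serializes every descriptor field with class names and rounded
#' percentages into a fixed-layout text prompt for a text backend, always
#' ending with a non-clinical disclaimer. Equal descriptors give
#' byte-identical prompts.
#'
#' @param d a [compute_descriptors()] result.
#' @param class_names one name per class (index order).
#' @return single character string.
#' @export
build_summary_prompt <- function(d, class_names) {
  if (length(class_names) < length(d$area_ratio)) {
    stopf("need %d class names, got %d", length(d$area_ratio), length(class_names))
  }
  lines <- c(
    "Summarize this segmented endoscopic scene in plain language.",
    sprintf("Image size: %d x %d pixels.", d$image_size[["height"]],
            d$image_size[["width"]]),
    "Per-class area:",
    sprintf("  - %s: %s%% of the image (%s)", class_names,
            formatC(round(100 * d$area_ratio, 1), format = "fg"),
            ifelse(d$presence, "present", "absent")),
    sprintf("Instrument touches the image border: %s.",
            ifelse(d$instrument_border_touch, "yes", "no")),
    sprintf("Blur indicator (variance of Laplacian): %.6g.", d$blur_score),
    paste("This summary is for non-clinical, illustrative use only and",
          "must not be used for clinical decision-making."))
  paste(lines, collapse = "\n")
}

#' Text-summarization backends
#'
#' A backend is any function mapping a prompt string to a text string. The
#' shipped `echo_backend` simply returns the prompt, which keeps the whole
#' pipeline runnable and testable offline; a large-language-model backend
#' can be plugged in with the same signature.
#'
#' @param prompt character string.
#' @export
echo_backend <- function(prompt) prompt

#' Summarize a segmented scene
#'
#' Convenience wrapper: descriptors, prompt, then the configured backend.
#'
#' @inheritParams compute_descriptors
#' @param class_names one name per class.
#' @param backend a function `prompt -> text` (default [echo_backend()]).
#' @return list with `descriptors`, `prompt`, `summary`.
#' @export
summarize_scene <- function(image, mask, class_names,
                            backend = echo_backend, ...) {
  d <- compute_descriptors(image, mask, num_classes = length(class_names), ...)
  prompt <- build_summary_prompt(d, class_names)
  list(descriptors = d, prompt = prompt, summary = backend(prompt))
}

#' @export
print.scene_descriptors <- function(x, ...) {
  cat("scene descriptors:\n")
  cat("  area ratios:", paste(sprintf("%.3f", x$area_ratio), collapse = " "), "\n")
  cat("  border touch:", x$instrument_border_touch,
      " blur score:", format(x$blur_score), "\n")
  invisible(x)
}

descriptors_to_json <- function(d, path = NULL) {
  obj <- list(area_ratio = d$area_ratio, presence = d$presence,
              instrument_border_touch = d$instrument_border_touch,
              blur_score = d$blur_score,
              image_size = as.list(d$image_size),
              instrument_class = d$instrument_class)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
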