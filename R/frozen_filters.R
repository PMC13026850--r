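#' Canonical frozen edge-filter bank
#'
#' Builds the fixed kernel bank used by the multi-filter frozen layer (MFFL):
#' the two Sobel first-derivative operators and the 4-neighbour Laplacian.
#' These kernels are never trained; they inject edge magnitude, edge
#' orientation and curvature information into the network while contributing
#' zero trainable parameters.
#'
#' All three kernels have zero DC response (entries sum to 0), so constant
#' image regions are annihilated and only structure survives.
#'
#' @return An object of class `frozen_kernel_bank`: a list with `kernels`
#'   (3x3x3 array, one 3x3 kernel per slice) and `names`
#'   (`"sobel_x"`, `"sobel_y"`, `"laplacian"`).
#' @examples
#' bank <- make_frozen_bank()
#' sapply(seq_len(3), function(k) sum(bank$kernels[, , k])) # all zero
#' @export
make_frozen_bank <- function() {
  sobel_x <- matrix(c(-1, -2, -1,
                       0,  0,  0,
                       1,  2,  1), 3, 3) # columns: -1 0 1 weights
  sobel_y <- t(sobel_x)
  laplacian <- matrix(c(0, 1, 0,
                        1, -4, 1,
                        0, 1, 0), 3, 3)
  kerns <- array(c(sobel_x, sobel_y, laplacian), dim = c(3, 3, 3))
  bank <- list(kernels = kerns, names = c("sobel_x", "sobel_y", "laplacian"))
  class(bank) <- "frozen_kernel_bank"
  bank
}

#' @export
print.frozen_kernel_bank <- function(x, ...) {
  cat("Frozen kernel bank (", length(x$names), " fixed 3x3 kernels):\n", sep = "")
  for (k in seq_along(x$names)) {
    cat("  ", x$names[k], ":\n", sep = "")
    print(x$kernels[, , k])
  }
  invisible(x)
}

#' Serialize / read a frozen bank as plain text
#'
#' Writes the kernel coefficients to a human-readable sidecar file so the
#' frozen weights of a checkpoint can be inspected without loading it.
#'
#' @param bank a `frozen_kernel_bank`.
#' @param path file path.
#' @export
write_frozen_bank <- function(bank, path) {
  lines <- unlist(lapply(seq_along(bank$names), function(k) {
    c(paste0("# ", bank$names[k]),
      apply(bank$kernels[, , k], 1, paste, collapse = " "))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_frozen_bank
#' @export
read_frozen_bank <- function(path) {
  lines <- readLines(path)
  nm <- sub("^# ", "", lines[grepl("^#", lines)])
  vals <- lines[!grepl("^#", lines)]
  rows <- lapply(strsplit(vals, " +"), as.numeric)
  kerns <- array(0, dim = c(3, 3, length(nm)))
  for (k in seq_along(nm)) {
    kerns[, , k] <- do.call(rbind, rows[(3 * k - 2):(3 * k)])
  }
  bank <- list(kernels = kerns, names = nm)
  class(bank) <- "frozen_kernel_bank"
  bank
}

#' Apply the frozen bank to a feature stack
#'
#' Convolves every input channel independently (depthwise) with each kernel
#' of the bank, producing `C * 3` output channels ordered channel-major,
#' kernel-minor: output channel `(c-1)*3 + k` is input channel `c` filtered
#' by kernel `k`. Borders are handled by reflective padding so responses
#' exist at every pixel without injecting an artificial frame edge. The
#' operation has no learnable parameters.
#'
#' @param features numeric array `H x W x C` or `H x W x C x N`, finite.
#' @param bank a `frozen_kernel_bank` (default: [make_frozen_bank()]).
#' @return array of the same spatial size with `C * 3` channels.
#' @export
apply_frozen_bank <- function(features, bank = make_frozen_bank()) {
  d <- dim(features)
  if (is.null(d) || length(d) < 2L) stopf("features must be an array")
  squeeze <- FALSE
  if (length(d) == 2L) { dim(features) <- c(d, 1L, 1L); squeeze <- TRUE }
  else if (length(d) == 3L) { dim(features) <- c(d, 1L); squeeze <- TRUE }
  d <- dim(features)
  if (d[1] < 3L || d[2] < 3L) stopf("input (%dx%d) smaller than the 3x3 kernels", d[1], d[2])
  if (!all(is.finite(features))) stopf("features contain non-finite values")
  out <- .cpp_frozen_fw(features, bank$kernels)
  if (squeeze && dim(out)[4] == 1L) dim(out) <- dim(out)[1:3]
  out
}
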