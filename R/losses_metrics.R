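#' Per-class confusion counts between two label masks
#'
#' One-vs-rest pixel counts per class: true/false positives and negatives
#' for each of the `num_classes` labels.
#'
#' @param pred,gt integer label masks of identical shape, labels in
#'   `[0, num_classes)`.
#' @param num_classes number of classes.
#' @return object of class `confusion_counts`: list with integer vectors
#'   `tp`, `fp`, `fn`, `tn` (one entry per class) and `total` pixels.
#' @export
confusion_counts <- function(pred, gt, num_classes) {
  if (!identical(dim(pred), dim(gt))) stopf("pred and gt shapes differ")
  pred <- as.integer(pred); gt <- as.integer(gt)
  K <- as.integer(num_classes)
  if (any(pred < 0L | pred >= K) || any(gt < 0L | gt >= K)) {
    stopf("labels outside [0, %d)", K)
  }
  total <- length(gt)
  joint <- tabulate(pred * K + gt + 1L, nbins = K * K)
  cm <- matrix(joint, nrow = K, byrow = TRUE) # rows = pred, cols = gt
  tp <- as.integer(diag(cm))
  fp <- as.integer(rowSums(cm) - tp)
  fn <- as.integer(colSums(cm) - tp)
  structure(list(tp = tp, fp = fp, fn = fn,
                 tn = as.integer(total - tp - fp - fn),
                 num_classes = K, total = total),
            class = "confusion_counts")
}

#' Combine confusion counts from several images
#'
#' Element-wise sum; used for micro-averaged metrics over a test split.
#' @param ... `confusion_counts` objects with equal `num_classes`.
#' @export
add_counts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) && !inherits(cs[[1]], "confusion_counts")) {
    cs <- cs[[1]]
  }
  out <- cs[[1]]
  for (cc in cs[-1]) {
    stopifnot(cc$num_classes == out$num_classes)
    for (f in c("tp", "fp", "fn", "tn")) out[[f]] <- out[[f]] + cc[[f]]
    out$total <- out$total + cc$total
  }
  out
}

#' Overlap metrics from confusion counts
#'
#' Computes, per class, intersection-over-union `I = tp / (tp + fp + fn)`,
#' Dice `D = 2 tp / (2 tp + fp + fn)`, precision `tp / (tp + fp)` and recall
#' `tp / (tp + fn)`, all in `[0, 1]`. The identity `D = 2 I / (1 + I)` holds
#' exactly for metrics derived from the same counts.
#'
#' Degenerate denominators: a class absent from both masks scores 1 on every
#' metric but is excluded from the `mean` row; a class predicted but absent
#' from the reference contributes through its false positives as usual.
#'
#' @param counts a [confusion_counts()] object.
#' @return object of class `seg_metrics`: a data.frame with one row per
#'   class plus a final `mean` row, columns `class`, `dice`, `iou`,
#'   `precision`, `recall` (fractions in `[0, 1]`).
#' @export
segmentation_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  absent <- (tp + fp + fn) == 0
  rat <- function(num, den) ifelse(den == 0, ifelse(absent, 1, 0), num / den)
  iou <- rat(tp, tp + fp + fn)
  dice <- rat(2 * tp, 2 * tp + fp + fn)
  pre <- rat(tp, tp + fp)
  rec <- rat(tp, tp + fn)
  keep <- !absent
  df <- data.frame(class = c(as.character(seq_along(tp) - 1L), "mean"),
                   dice = c(dice, mean(dice[keep])),
                   iou = c(iou, mean(iou[keep])),
                   precision = c(pre, mean(pre[keep])),
                   recall = c(rec, mean(rec[keep])))
  class(df) <- c("seg_metrics", "data.frame")
  df
}

# boundary pixels: labelled `lab` and 4-adjacent (within the image) to a
# pixel of any other label
boundary_of <- function(mask, lab) {
  H <- nrow(mask); W <- ncol(mask)
  m <- mask == lab
  nb_diff <- matrix(FALSE, H, W)
  nb_diff[-1, ] <- nb_diff[-1, ] | (mask[-1, ] != mask[-H, ])
  nb_diff[-H, ] <- nb_diff[-H, ] | (mask[-H, ] != mask[-1, ])
  nb_diff[, -1] <- nb_diff[, -1] | (mask[, -1] != mask[, -W])
  nb_diff[, -W] <- nb_diff[, -W] | (mask[, -W] != mask[, -1])
  m & nb_diff
}

#' Boundary F1 score
#'
#' F1 over boundary pixels with a distance tolerance: a predicted boundary
#' pixel counts as matched when some reference boundary pixel of the same
#' class lies within Euclidean distance `tolerance`, and vice versa.
#' Boundaries are foreground pixels 4-adjacent to a different label. The
#' score is averaged over the non-background classes present in either
#' mask. Conventions: both masks empty of a class's boundary gives 1 for
#' that class; only one empty gives 0.
#'
#' @param pred,gt integer label masks of identical shape.
#' @param tolerance match radius in pixels; default 0.75% of the image
#'   diagonal, rounded up.
#' @return value in `[0, 1]`.
#' @export
bf_score <- function(pred, gt, tolerance = NULL) {
  if (!identical(dim(pred), dim(gt))) stopf("pred and gt shapes differ")
  H <- nrow(gt); W <- ncol(gt)
  if (is.null(tolerance)) tolerance <- ceiling(0.0075 * sqrt(H^2 + W^2))
  classes <- setdiff(sort(unique(c(as.integer(pred), as.integer(gt)))), 0L)
  if (!length(classes)) return(1)
  scores <- vapply(classes, function(k) {
    pb <- boundary_of(pred, k)
    gb <- boundary_of(gt, k)
    if (!any(pb) && !any(gb)) return(1)
    if (!any(pb) || !any(gb)) return(0)
    # exact Euclidean distance-to-boundary maps
    dg <- EBImage::distmap(1 - gb)
    dp <- EBImage::distmap(1 - pb)
    precision <- mean(dg[pb] <= tolerance)
    recall <- mean(dp[gb] <= tolerance)
    if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  }, numeric(1))
  mean(scores)
}

#' Inverse-frequency class weights
#'
#' `w_k = T / (K * c_k)` where `T` is the total pixel count, `K` the number
#' of classes and `c_k` the per-class pixel count floored at 1 (so absent
#' classes get a finite weight). Balanced classes give unit weights.
#'
#' @param label_frequency per-class pixel counts (at least one nonzero).
#' @return object of class `class_weights` (positive numeric vector).
#' @export
compute_class_weights <- function(label_frequency) {
  cnt <- as.numeric(label_frequency)
  if (all(cnt == 0)) stopf("all class counts are zero")
  Tt <- sum(cnt)
  cnt <- pmax(cnt, 1)
  w <- Tt / (length(cnt) * cnt)
  structure(w, class = "class_weights")
}

one_hot_mask <- function(gt, K) {
  d <- dim(gt)
  if (length(d) == 2L) d <- c(d, 1L)
  oh <- array(0, dim = c(d[1], d[2], K, d[3]))
  for (k in seq_len(K)) oh[, , k, ] <- as.numeric(gt == (k - 1L))
  oh
}

check_probs <- function(probs, gt) {
  d <- dim(probs)
  if (length(d) == 3L) dim(probs) <- c(d, 1L)
  if (!all(is.finite(probs))) stopf("probabilities contain non-finite values")
  gt <- as.array(gt)
  if (length(dim(gt)) == 2L) dim(gt) <- c(dim(gt), 1L)
  list(probs = probs, gt = gt)
}

#' Class-weighted cross-entropy loss
#'
#' Mean over pixels of `-w[gt] * log(p[gt])` with probabilities clipped to
#' `[1e-7, 1]`. Unit weights recover plain cross-entropy; doubling one
#' class's weight exactly doubles the contribution of its pixels.
#'
#' @param probs `H x W x K (x N)` softmax probabilities.
#' @param gt integer label mask(s), 0-based.
#' @param w per-class weights (default all 1).
#' @return scalar loss (>= 0).
#' @export
weighted_cross_entropy <- function(probs, gt, w = NULL) {
  ck <- check_probs(probs, gt)
  K <- dim(ck$probs)[3]
  if (is.null(w)) w <- rep(1, K)
  oh <- one_hot_mask(ck$gt, K)
  pg <- pmax(apply_over_classes_sum(ck$probs * oh), 1e-7)
  wg <- array(as.numeric(w[as.integer(ck$gt) + 1L]), dim = dim(ck$gt))
  mean(-wg * log(pg))
}

# class-k slice of an (H, W, K, N) array, kept as (H, W, N)
slice_k <- function(x, k) {
  d <- dim(x)
  y <- x[, , k, , drop = FALSE]
  dim(y) <- c(d[1], d[2], d[4])
  y
}

# sum over the class dimension of (H, W, K, N) -> (H, W, N)
apply_over_classes_sum <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[4]))
  for (k in seq_len(d[3])) out <- out + slice_k(x, k)
  out
}

#' Class-weighted soft Dice loss
#'
#' `1 - sum_k w_k S_k / sum_k w_k` where `S_k` is the smoothed soft Dice of
#' class `k`: `(2 * sum p_k g_k + eps) / (sum p_k + sum g_k + eps)`, with
#' one-hot ground truth `g` and `eps = 1e-5`. Lies in `[0, 1]`; 0 at exact
#' (soft) agreement.
#'
#' @inheritParams weighted_cross_entropy
#' @export
weighted_dice_loss <- function(probs, gt, w = NULL) {
  ck <- check_probs(probs, gt)
  K <- dim(ck$probs)[3]
  if (is.null(w)) w <- rep(1, K)
  eps <- 1e-5
  oh <- one_hot_mask(ck$gt, K)
  s <- vapply(seq_len(K), function(k) {
    pk <- ck$probs[, , k, ]; gk <- oh[, , k, ]
    (2 * sum(pk * gk) + eps) / (sum(pk) + sum(gk) + eps)
  }, numeric(1))
  1 - sum(w * s) / sum(w)
}

# loss value plus gradient w.r.t. logits, for the training loop
loss_and_grad <- function(kind, logits, gt, w) {
  probs <- softmax_channels(logits)
  d <- dim(probs)
  K <- d[3]
  gt <- as.array(gt)
  if (length(dim(gt)) == 2L) dim(gt) <- c(dim(gt), 1L)
  oh <- one_hot_mask(gt, K)
  if (kind == "weighted_ce") {
    loss <- weighted_cross_entropy(probs, gt, w)
    n_pix <- d[1] * d[2] * d[4]
    wg <- array(as.numeric(w[as.integer(gt) + 1L]), dim = c(d[1], d[2], d[4]))
    dlogits <- array(0, dim = d)
    for (k in seq_len(K)) {
      dlogits[, , k, ] <- wg * (slice_k(probs, k) - slice_k(oh, k)) / n_pix
    }
  } else if (kind == "weighted_dice") {
    eps <- 1e-5
    sw <- sum(w)
    dprobs <- array(0, dim = d)
    sk <- numeric(K)
    for (k in seq_len(K)) {
      pk <- slice_k(probs, k); gk <- slice_k(oh, k)
      A <- sum(pk * gk); B <- sum(pk) + sum(gk)
      sk[k] <- (2 * A + eps) / (B + eps)
      dprobs[, , k, ] <- -(w[k] / sw) * (2 * gk * (B + eps) - (2 * A + eps)) / (B + eps)^2
    }
    loss <- 1 - sum(w * sk) / sw
    # chain through the per-pixel softmax
    dot <- apply_over_classes_sum(dprobs * probs)
    dlogits <- array(0, dim = d)
    for (k in seq_len(K)) {
      dlogits[, , k, ] <- slice_k(probs, k) * (slice_k(dprobs, k) - dot)
    }
  } else {
    stopf("unknown loss kind '%s'", kind)
  }
  list(loss = loss, dlogits = dlogits)
}

#' True/false positive overlay image
#'
#' Paints the standard error-analysis overlay over a dimmed grayscale copy
#' of the input: true positives blue, false positives green, false
#' negatives red.
#'
#' @param pred,gt binary masks (0/1) of the foreground class.
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
error_overlay <- function(pred, gt, image) {
  if (!identical(dim(pred), dim(gt)) || !identical(dim(pred), dim(image)[1:2])) {
    stopf("pred, gt and image spatial shapes differ")
  }
  pred <- pred > 0; gt <- gt > 0
  gray <- 0.4 * (0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  out <- array(rep(gray, 3), dim = dim(image))
  tp <- pred & gt; fp <- pred & !gt; fn <- !pred & gt
  paint <- function(out, sel, rgb) {
    for (c in 1:3) {
      ch <- out[, , c]; ch[sel] <- rgb[c]; out[, , c] <- ch
    }
    out
  }
  out <- paint(out, tp, c(0, 0, 1))
  out <- paint(out, fp, c(0, 1, 0))
  out <- paint(out, fn, c(1, 0, 0))
  out
}

#' Write a metrics table as CSV
#'
#' Values are scaled to percentages (x100) to match the conventional
#' reporting format for segmentation benchmarks.
#'
#' @param metrics a `seg_metrics` data.frame or a per-fold table from
#'   [cross_validate()].
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(metrics, path) {
  df <- as.data.frame(metrics)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(100 * v, 2))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
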