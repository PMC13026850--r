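# Independent brute-force oracles used across tests. These deliberately
# re-derive results with direct nested-loop arithmetic so they share no code
# with the package's vectorised / GEMM-based implementations.

# direct 2-D 3x3 convolution with reflective borders
naive_conv3 <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  refl <- function(p, n) {
    if (p < 1) p <- 2 - p
    if (p > n) p <- 2 * n - p
    p
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      s <- 0
      for (a in 1:3) {
        for (b in 1:3) {
          s <- s + img[refl(i + a - 2, H), refl(j + b - 2, W)] * k[a, b]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# all-pairs boundary F1: boundary = foreground pixels 4-adjacent (in image)
# to a different label; a boundary pixel matches if any opposite boundary
# pixel lies within Euclidean distance <= tol
naive_bf1 <- function(pred, gt, tol) {
  bnd <- function(mask, k) {
    H <- nrow(mask); W <- ncol(mask)
    px <- NULL
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        if (mask[i, j] != k) next
        nb <- FALSE
        if (i > 1 && mask[i - 1, j] != k) nb <- TRUE
        if (i < H && mask[i + 1, j] != k) nb <- TRUE
        if (j > 1 && mask[i, j - 1] != k) nb <- TRUE
        if (j < W && mask[i, j + 1] != k) nb <- TRUE
        if (nb) px <- rbind(px, c(i, j))
      }
    }
    px
  }
  match_frac <- function(a, b, tol) {
    mean(apply(a, 1, function(p) {
      min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2)) <= tol
    }))
  }
  classes <- setdiff(sort(unique(c(pred, gt))), 0L)
  if (!length(classes)) return(1)
  mean(sapply(classes, function(k) {
    pb <- bnd(pred, k); gb <- bnd(gt, k)
    if (is.null(pb) && is.null(gb)) return(1)
    if (is.null(pb) || is.null(gb)) return(0)
    pr <- match_frac(pb, gb, tol)
    rc <- match_frac(gb, pb, tol)
    if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }))
}

# small scene preset shared by training-based tests: 64x64 keeps runtimes low
small_scene_spec <- function(...) {
  scene_spec(height = 64, width = 64,
             instrument_width_range = c(5, 12),
             instrument_length_range = c(30, 80), ...)
}

tiny_network_config <- function(...) {
  args <- utils::modifyList(
    list(input_height = 16, input_width = 16, num_classes = 2,
         stem_width = 3, encoder_widths = c(4, 5, 6),
         tab_width = 4, decoder_widths = c(5, 4, 3)),
    list(...))
  do.call(network_config, args)
}
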