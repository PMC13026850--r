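test_that("config validation rejects malformed plans", {
  expect_error(network_config(input_height = 100), "divisible by 8")
  expect_error(network_config(num_classes = 1), "num_classes")
  expect_error(network_config(stem_width = 0), "positive")
  expect_error(network_config(tab_dilations = c(4, 2, 6)), "increasing")
})

test_that("output resolution equals input resolution and softmax normalizes", {
  cfg <- tiny_network_config()
  m <- build_network(cfg, seed = 1)
  set.seed(1)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  p <- forward(m, x)
  expect_identical(dim(p), c(16L, 16L, 2L, 2L))
  sums <- p[, , 1, ] + p[, , 2, ]
  expect_lt(max(abs(sums - 1)), 1e-5)
  # a second, non-square-free size
  cfg2 <- tiny_network_config(input_height = 24, input_width = 32)
  m2 <- build_network(cfg2, seed = 1)
  p2 <- forward(m2, array(runif(24 * 32 * 3), c(24, 32, 3)))
  expect_identical(dim(p2), c(24L, 32L, 2L))
})

test_that("inference is deterministic and batch-composition invariant", {
  m <- build_network(tiny_network_config(), seed = 3)
  set.seed(9)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  p1 <- forward(m, x)
  p2 <- forward(m, x)
  expect_identical(p1, p2)
  pa <- forward(m, x[, , , 1, drop = FALSE])
  expect_lt(max(abs(p1[, , , 1] - pa[, , , 1])), 1e-5)
})

test_that("trainable parameter count matches a closed-form layer audit", {
  # single conv: k*k*Cin*Cout + Cout
  conv_p <- function(k, ci, co) k * k * ci * co + co
  bn_p <- function(c) 2 * c
  cfg <- network_config() # 3 channels in, 2 classes, default widths
  m <- build_network(cfg)
  sw <- 16; ew <- c(32, 64, 128); tw <- 64; dw <- c(64, 32, 16)
  expected <-
    conv_p(3, 3, sw) + bn_p(sw) + conv_p(3, sw, sw) + bn_p(sw) + # stem learnable
    conv_p(1, 3, sw) +                                           # FFU point-wise
    conv_p(1, 4 * sw, sw) + bn_p(sw) +                           # squeeze
    conv_p(3, sw, ew[1]) + conv_p(3, ew[1], ew[1]) + bn_p(ew[1]) +
    conv_p(3, ew[1], ew[2]) + conv_p(3, ew[2], ew[2]) + bn_p(ew[2]) +
    conv_p(3, ew[2], ew[3]) + conv_p(3, ew[3], ew[3]) + bn_p(ew[3]) +
    3 * (conv_p(3, ew[3], tw) + conv_p(1, tw, tw)) +             # atrous streams
    conv_p(3, 3 * tw, ew[3]) + bn_p(ew[3]) +                     # bottleneck fuse
    sum(sapply(1:3, function(s) {
      din <- c(ew[3], dw[1], dw[2])[s]
      skip <- c(ew[2], ew[1], sw)[s]
      4 * 4 * dw[s] * din + dw[s] +                              # transposed conv
        conv_p(1, skip, dw[s]) + bn_p(dw[s]) +                   # light skip path
        2 * conv_p(3, 2 * dw[s], dw[s]) +                        # dilated + standard
        conv_p(3, dw[s], dw[s]) + bn_p(dw[s])                    # fusion conv
    })) +
    conv_p(1, dw[3], 2)                                          # classifier head
  expect_identical(count_trainable_params(m), expected)
  # one isolated convolution as a sanity anchor: 3x3, 3 -> 8 with bias
  expect_identical(conv_p(3, 3, 8), 224)
})

test_that("default configuration stays within the 1.5 M parameter budget", {
  m <- build_network(network_config())
  expect_lte(count_trainable_params(m), 1.5e6)
  expect_gte(count_trainable_params(m), 1.0e6)
  expect_error(build_network(network_config(), max_params = 1e5), "budget")
})

test_that("ablation variants drop the matching sub-graphs", {
  m_full <- build_network(tiny_network_config(), seed = 1)
  m_noflfp <- build_network(tiny_network_config(enable_flfp = FALSE), seed = 1)
  expect_null(m_noflfp$frozen)
  expect_false(any(grepl("mffl|ffu", names(m_noflfp$params))))
  m_notab <- build_network(tiny_network_config(enable_tab = FALSE), seed = 1)
  expect_false(any(grepl("atrous", names(m_notab$params))))
  m_nofus <- build_network(tiny_network_config(enable_pspd_fusion = FALSE), seed = 1)
  expect_false(any(grepl("lsp|\\.di\\.|\\.std\\.", names(m_nofus$params))))
  expect_lt(count_trainable_params(m_nofus), count_trainable_params(m_full))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_network_config()
  m <- build_network(cfg, seed = 7)
  set.seed(2)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  gt <- array(sample(0:1, 256, TRUE), c(16, 16, 1))
  w <- c(1, 2)
  for (kind in c("weighted_ce", "weighted_dice")) {
    fw <- ffmsnet:::net_forward(m, x, training = TRUE)
    lg <- ffmsnet:::loss_and_grad(kind, fw$logits, gt, w)
    grads <- ffmsnet:::net_backward(m, fw, lg$dlogits)
    loss_of <- function(model) {
      f <- ffmsnet:::net_forward(model, x, training = TRUE)
      ffmsnet:::loss_and_grad(kind, f$logits, gt, w)$loss
    }
    set.seed(4)
    for (nm in sample(names(m$params), 8)) {
      i <- sample(length(m$params[[nm]]), 1)
      eps <- 1e-5
      m_p <- m; m_p$params[[nm]][i] <- m$params[[nm]][i] + eps
      m_m <- m; m_m$params[[nm]][i] <- m$params[[nm]][i] - eps
      num <- (loss_of(m_p) - loss_of(m_m)) / (2 * eps)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-6 + 1e-4 * (abs(num) + abs(ana)))
    }
  }
})

test_that("predict_mask takes the argmax with low-index tie-breaks", {
  p <- array(0, c(1, 1, 2))
  p[1, 1, ] <- c(0.7, 0.3)
  expect_identical(predict_mask(p), matrix(0L, 1, 1))
  p[1, 1, ] <- c(0.5, 0.5)
  expect_identical(predict_mask(p), matrix(0L, 1, 1))
  # inverse of one-hot encoding
  set.seed(8)
  gt <- matrix(sample(0:2, 36, TRUE), 6, 6)
  oh <- ffmsnet:::one_hot_mask(gt, 3)
  expect_identical(predict_mask(oh[, , , 1]), gt)
})

test_that("checkpoints round-trip the whole model", {
  path <- withr::local_tempfile(fileext = ".rds")
  m <- build_network(tiny_network_config(), seed = 5)
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  set.seed(1)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(forward(m, x), forward(m2, x))
})

test_that("network config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- network_config(stem_width = 8, tab_dilations = c(1, 3, 5))
  write_network_config(cfg, path)
  cfg2 <- read_network_config(path)
  expect_equal(unclass(cfg), unclass(cfg2))
})
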