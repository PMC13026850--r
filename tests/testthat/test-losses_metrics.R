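test_that("confusion counts follow one-vs-rest pixel bookkeeping", {
  gt <- matrix(0L, 4, 4); gt[1:3, 1:3] <- 1L      # 9 foreground, adjust to 10
  gt[4, 1] <- 1L                                   # 10 gt-foreground pixels
  pred <- matrix(0L, 4, 4); pred[1:3, 1:3] <- 1L   # 9 shared minus...
  pred[1, 4] <- 1L                                 # extra prediction
  # shared fg = 9, pred-only = 1, gt-only = 1
  cc <- confusion_counts(pred, gt, 2)
  expect_equal(cc$tp[2], 9)
  expect_equal(cc$fp[2], 1)
  expect_equal(cc$fn[2], 1)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, rep(16, 2))
  # identity
  cc2 <- confusion_counts(gt, gt, 2)
  expect_equal(cc2$fp, c(0, 0)); expect_equal(cc2$fn, c(0, 0))
  # disjoint: all-background pred vs all-foreground gt
  cc3 <- confusion_counts(matrix(0L, 4, 4), matrix(1L, 4, 4), 2)
  expect_equal(cc3$tp[2], 0); expect_equal(cc3$fn[2], 16); expect_equal(cc3$fp[2], 0)
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(5L, 2, 2), 2), "labels")
})

test_that("overlap metrics reproduce the tp/fp/fn identities", {
  # tp=8, fp=2, fn=2 toy: I = 8/12, D = 16/20
  gt <- matrix(0L, 4, 4); gt[1:2, 1:4] <- 1L; gt[3, 1:2] <- 1L # 10 fg
  pred <- matrix(0L, 4, 4); pred[1:2, 1:4] <- 1L; pred[4, 3:4] <- 1L
  cc <- confusion_counts(pred, gt, 2)
  expect_equal(c(cc$tp[2], cc$fp[2], cc$fn[2]), c(8, 2, 2))
  met <- segmentation_metrics(cc)
  expect_equal(met$iou[2], 2 / 3)
  expect_equal(met$dice[2], 0.8)
  # D = 2I/(1+I) exactly, all classes
  expect_equal(met$dice[1:2], 2 * met$iou[1:2] / (1 + met$iou[1:2]))
  # identical masks give all-ones; disjoint masks give zero overlap
  expect_equal(segmentation_metrics(confusion_counts(gt, gt, 2))$dice[1:2], c(1, 1))
  dis <- segmentation_metrics(confusion_counts(1L - gt, gt, 2))
  expect_equal(dis$dice[2], 0)
  expect_equal(dis$iou[2], 0)
})

test_that("the Dice/IoU identity holds on random masks and absent classes score 1", {
  set.seed(33)
  for (r in 1:20) {
    pred <- matrix(sample(0:2, 64, TRUE), 8, 8)
    gt <- matrix(sample(0:2, 64, TRUE), 8, 8)
    met <- segmentation_metrics(confusion_counts(pred, gt, 4))
    pc <- met[met$class != "mean", ]
    expect_equal(pc$dice, 2 * pc$iou / (1 + pc$iou))
    expect_true(all(pc$dice >= 0 & pc$dice <= 1))
    # class 3 never occurs: scores 1, excluded from the mean
    expect_equal(pc$dice[4], 1)
    expect_equal(met$dice[met$class == "mean"],
                 mean(pc$dice[1:3]))
  }
})

test_that("boundary F1 matches the brute-force all-pairs oracle", {
  # shifted square within tolerance
  gt <- matrix(0L, 8, 8); gt[3:6, 3:6] <- 1L
  pred <- matrix(0L, 8, 8); pred[3:6, 4:7] <- 1L
  expect_equal(bf_score(pred, gt, tolerance = 2), 1.0)
  expect_equal(bf_score(gt, gt, tolerance = 1), 1.0)
  expect_equal(bf_score(matrix(0L, 8, 8), gt, tolerance = 2), 0.0)
  expect_equal(bf_score(matrix(0L, 8, 8), matrix(0L, 8, 8)), 1.0)
  set.seed(77)
  for (r in 1:20) {
    pred <- matrix(as.integer(matrix(runif(256), 16, 16) > 0.6), 16, 16)
    gt <- matrix(as.integer(matrix(runif(256), 16, 16) > 0.6), 16, 16)
    tol <- sample(1:3, 1)
    expect_equal(bf_score(pred, gt, tolerance = tol), naive_bf1(pred, gt, tol))
  }
})

test_that("class weights are inverse-frequency with a unit-count floor", {
  expect_equal(as.numeric(compute_class_weights(c(50, 50))), c(1, 1))
  w <- as.numeric(compute_class_weights(c(90, 10)))
  expect_equal(w, c(100 / 180, 100 / 20))
  expect_equal(w[2] / w[1], 9)
  w0 <- as.numeric(compute_class_weights(c(100, 0)))
  expect_true(all(is.finite(w0)) && all(w0 > 0))
  expect_error(compute_class_weights(c(0, 0)), "zero")
})

test_that("cross-entropy honours its clipping, uniform and linearity contracts", {
  set.seed(12)
  gt <- matrix(sample(0:1, 64, TRUE), 8, 8)
  perfect <- ffmsnet:::one_hot_mask(gt, 2)[, , , 1]
  expect_lte(weighted_cross_entropy(perfect, gt), 1e-6)
  uniform <- array(0.5, c(8, 8, 2))
  expect_equal(weighted_cross_entropy(uniform, gt), log(2), tolerance = 1e-12)
  # doubling one class's weight doubles exactly that class's contribution
  l_unit <- weighted_cross_entropy(uniform, gt, c(1, 1))
  l_w <- weighted_cross_entropy(uniform, gt, c(1, 2))
  frac1 <- mean(gt == 1)
  expect_equal(l_w, log(2) * (1 - frac1) + 2 * log(2) * frac1, tolerance = 1e-12)
  expect_equal(l_unit, weighted_cross_entropy(uniform, gt, NULL))
})

test_that("soft Dice loss matches a direct summation of its formula", {
  gt <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  probs <- array(0.5, c(2, 2, 2))
  # direct evaluation: for each class, (2*sum(p*g)+eps)/(sum p + sum g + eps)
  eps <- 1e-5
  s0 <- (2 * 0.5 * 2 + eps) / (0.5 * 4 + 2 + eps)
  s1 <- (2 * 0.5 * 2 + eps) / (0.5 * 4 + 2 + eps)
  expect_equal(weighted_dice_loss(probs, gt), 1 - (s0 + s1) / 2, tolerance = 1e-12)
  # exact agreement and total disagreement
  oh <- ffmsnet:::one_hot_mask(gt, 2)[, , , 1]
  expect_lte(weighted_dice_loss(oh, gt), 1e-4)
  expect_gte(weighted_dice_loss(oh, 1L - gt), 0.999)
})

test_that("both losses stay in [0, 1] on random inputs", {
  set.seed(55)
  for (r in 1:100) {
    K <- sample(2:4, 1)
    raw <- array(runif(6 * 6 * K), c(6, 6, K))
    s <- array(0, c(6, 6))
    for (k in 1:K) s <- s + raw[, , k]
    for (k in 1:K) raw[, , k] <- raw[, , k] / s
    gt <- matrix(sample(0:(K - 1), 36, TRUE), 6, 6)
    dl <- weighted_dice_loss(raw, gt)
    expect_gte(dl, 0); expect_lte(dl, 1)
    ce <- weighted_cross_entropy(raw, gt)
    expect_gte(ce, 0)
  }
})

test_that("error overlay paints tp blue, fp green, fn red", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  gt <- matrix(0L, 8, 8); gt[2:5, 2:5] <- 1L
  pred <- matrix(0L, 8, 8); pred[3:6, 2:5] <- 1L
  ov <- error_overlay(pred, gt, img)
  tp <- pred == 1 & gt == 1; fp <- pred == 1 & gt == 0; fn <- pred == 0 & gt == 1
  expect_true(all(ov[, , 3][tp] == 1) && all(ov[, , 1][tp] == 0))
  expect_true(all(ov[, , 2][fp] == 1) && all(ov[, , 3][fp] == 0))
  expect_true(all(ov[, , 1][fn] == 1) && all(ov[, , 2][fn] == 0))
  # perfect prediction: only blue paint
  ov2 <- error_overlay(gt, gt, img)
  expect_true(all(ov2[, , 3][gt == 1] == 1))
  expect_true(all(ov2[, , 2][gt == 1] == 0))
  # all-foreground pred vs empty gt: only green
  ov3 <- error_overlay(matrix(1L, 8, 8), matrix(0L, 8, 8), img)
  expect_true(all(ov3[, , 2] == 1) && all(ov3[, , 1] == 0))
})
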