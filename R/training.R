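#' Training configuration
#'
#' Optimization protocol: Adam with a step-decayed learning rate, L2 weight
#' decay on convolution weights, per-epoch reshuffling. Defaults follow the
#' protocol the architecture was developed under: initial learning rate
#' 5e-4, decayed by a factor 0.1 every 10 epochs, L2 regularization 5e-4.
#'
#' @param initial_lr initial learning rate (> 0).
#' @param lr_drop_period epochs between learning-rate drops.
#' @param lr_drop_factor multiplicative drop factor in (0, 1].
#' @param l2 weight-decay coefficient, applied to convolution and
#'   transposed-convolution weights only (not biases or batch-norm
#'   scales/shifts).
#' @param batch_size minibatch size (>= 1).
#' @param epochs number of epochs.
#' @param loss_kind `"weighted_ce"` (class-weighted cross-entropy, suited to
#'   binary instrument/background tasks) or `"weighted_dice"` (class-weighted
#'   soft Dice, suited to multi-class tasks with severe imbalance).
#' @param shuffle_each_epoch reshuffle the training order every epoch.
#' @param seed optional integer controlling shuffling (and, through
#'   [build_network()], initialization when the caller passes the same seed).
#' @return object of class `train_config`.
#' @export
train_config <- function(initial_lr = 5e-4, lr_drop_period = 10L,
                         lr_drop_factor = 0.1, l2 = 5e-4,
                         batch_size = 4L, epochs = 30L,
                         loss_kind = c("weighted_ce", "weighted_dice"),
                         shuffle_each_epoch = TRUE, seed = NULL) {
  loss_kind <- match.arg(loss_kind)
  if (initial_lr <= 0) stopf("initial_lr must be > 0")
  if (lr_drop_factor <= 0 || lr_drop_factor > 1) stopf("lr_drop_factor must be in (0, 1]")
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  structure(list(initial_lr = initial_lr,
                 lr_drop_period = as.integer(lr_drop_period),
                 lr_drop_factor = lr_drop_factor, l2 = l2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss_kind = loss_kind,
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "train_config")
}

#' Step-decayed learning rate at a given epoch
#'
#' `initial_lr * lr_drop_factor ^ floor((epoch - 1) / lr_drop_period)`:
#' 5e-4 for epochs 1-10, 5e-5 for 11-20, 5e-6 for 21-30 under the defaults.
#'
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch index.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(all(epoch >= 1))
  cfg$initial_lr * cfg$lr_drop_factor^(floor((epoch - 1) / cfg$lr_drop_period))
}

#' Random k-fold partition
#'
#' Permutes the sample indices under `seed` and assigns folds round-robin,
#' so folds are disjoint, cover all samples, and differ in size by at most
#' one.
#'
#' @param n sample count.
#' @param k fold count (default 5).
#' @param seed integer seed; the same `(n, k, seed)` always gives the same
#'   assignment.
#' @return object of class `fold_split`: list with `k` and the per-sample
#'   integer `assignment` in `1..k`.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (n < k) stopf("need at least as many samples (%d) as folds (%d)", n, k)
  if (k < 2L) stopf("k must be >= 2")
  perm <- with_seed(seed, sample.int(n))
  assignment <- integer(n)
  assignment[perm] <- rep_len(seq_len(k), n)
  structure(list(k = as.integer(k), assignment = assignment),
            class = "fold_split")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       v = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, l2, decay_names,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (l2 > 0 && nm %in% decay_names) g <- g + l2 * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    p_new <- params[[nm]] - step
    dim(p_new) <- dim(params[[nm]])
    params[[nm]] <- p_new
  }
  list(params = params, opt = opt)
}

pairs_to_batch <- function(pairs, idx) {
  d <- dim(pairs[[idx[1]]]$image)
  x <- array(0, dim = c(d[1], d[2], d[3], length(idx)))
  g <- array(0L, dim = c(d[1], d[2], length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- pairs[[idx[j]]]$image
    g[, , j] <- pairs[[idx[j]]]$mask
  }
  list(x = x, gt = g)
}

class_pixel_counts <- function(pairs, K) {
  cnt <- numeric(K)
  for (p in pairs) cnt <- cnt + tabulate(as.integer(p$mask) + 1L, nbins = K)
  cnt
}

#' Train a segmentation model
#'
#' Runs Adam on the trainable parameters (the frozen kernel bank is never
#' touched), with the step-decayed learning-rate schedule of
#' [lr_at_epoch()], L2 weight decay on convolution weights, and per-epoch
#' reshuffling of the training order. Class weights for the loss are
#' computed from the training-set label frequencies via
#' [compute_class_weights()] unless supplied.
#'
#' @param model a `seg_model` from [build_network()].
#' @param train_pairs list of samples, each a list with `image`
#'   (`H x W x C`, values in `[0, 1]`) and `mask` (`H x W` integer labels).
#' @param val_pairs optional held-out samples; per-epoch mean foreground
#'   Dice on them is recorded in the history.
#' @param cfg a [train_config()].
#' @param class_weights optional per-class loss weights.
#' @param verbose print per-epoch progress.
#' @return list with the trained `model` and a `history` data.frame-based
#'   record: `$iter_loss` (per-iteration training loss), `$epoch` (per-epoch
#'   learning rate, mean loss, pixel accuracy and, when `val_pairs` is
#'   given, validation Dice).
#' @export
train_model <- function(model, train_pairs, val_pairs = NULL, cfg,
                        class_weights = NULL, verbose = FALSE) {
  if (!length(train_pairs)) stopf("empty training set")
  K <- model$cfg$num_classes
  if (is.null(class_weights)) {
    class_weights <- compute_class_weights(class_pixel_counts(train_pairs, K))
  }
  opt <- adam_init(model$params)
  n <- length(train_pairs)
  iter_loss <- numeric(0)
  ep_lr <- numeric(cfg$epochs)
  ep_loss <- numeric(cfg$epochs)
  ep_acc <- numeric(cfg$epochs)
  ep_val_dice <- rep(NA_real_, cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch)
    ep_lr[epoch] <- lr
    ord <- if (cfg$shuffle_each_epoch) {
      with_seed(child_seed(cfg$seed, epoch), sample.int(n))
    } else seq_len(n)
    losses <- numeric(0)
    acc_num <- 0; acc_den <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      batch <- pairs_to_batch(train_pairs, idx)
      fw <- net_forward(model, batch$x, training = TRUE)
      model <- fw$model # batch-norm running statistics advanced
      lg <- loss_and_grad(cfg$loss_kind, fw$logits, batch$gt, class_weights)
      if (!is.finite(lg$loss)) {
        stopf("non-finite loss (%g) at epoch %d; aborting", lg$loss, epoch)
      }
      grads <- net_backward(model, fw, lg$dlogits)
      upd <- adam_step(model$params, grads, opt, lr, cfg$l2, model$decay_params)
      model$params <- upd$params
      opt <- upd$opt
      losses <- c(losses, lg$loss)
      pm <- predict_mask(softmax_channels(fw$logits))
      acc_num <- acc_num + sum(pm == batch$gt)
      acc_den <- acc_den + length(batch$gt)
    }
    iter_loss <- c(iter_loss, losses)
    ep_loss[epoch] <- mean(losses)
    ep_acc[epoch] <- acc_num / acc_den
    if (!is.null(val_pairs)) {
      ep_val_dice[epoch] <- mean_foreground_dice(model, val_pairs)
    }
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.4f%s", epoch, lr,
                      ep_loss[epoch], ep_acc[epoch],
                      if (is.na(ep_val_dice[epoch])) "" else
                        sprintf("  val dice %.4f", ep_val_dice[epoch])))
    }
  }
  history <- list(iter_loss = iter_loss,
                  epoch = data.frame(epoch = seq_len(cfg$epochs), lr = ep_lr,
                                     loss = ep_loss, pixel_acc = ep_acc,
                                     val_dice = ep_val_dice))
  list(model = model, history = history)
}

# micro-averaged mean Dice over foreground classes of a set of pairs
mean_foreground_dice <- function(model, pairs) {
  met <- evaluate_model(model, pairs)
  fg <- met$class != "mean" & met$class != "0"
  mean(met$dice[fg])
}

#' Evaluate a model on labelled pairs
#'
#' Accumulates confusion counts over the whole set (micro averaging) and
#' derives the overlap metrics; optionally also the mean boundary F1.
#' Per-image averaging is available for comparison with protocols that
#' report it.
#'
#' @param model a `seg_model`.
#' @param pairs list of `image`/`mask` samples.
#' @param average `"micro"` (pool counts, then compute metrics) or
#'   `"per_image"` (compute per image, then average).
#' @param bf1 also compute the mean boundary-F1 column.
#' @return a `seg_metrics` data.frame (see [segmentation_metrics()]).
#' @export
evaluate_model <- function(model, pairs, average = c("micro", "per_image"),
                           bf1 = FALSE) {
  average <- match.arg(average)
  K <- model$cfg$num_classes
  counts <- NULL
  per_image <- list()
  bfs <- numeric(0)
  for (p in pairs) {
    pm <- segment(model, p$image)
    cc <- confusion_counts(pm, p$mask, K)
    if (average == "micro") {
      counts <- if (is.null(counts)) cc else add_counts(counts, cc)
    } else {
      per_image[[length(per_image) + 1L]] <- segmentation_metrics(cc)
    }
    if (bf1) bfs <- c(bfs, bf_score(pm, p$mask))
  }
  met <- if (average == "micro") {
    segmentation_metrics(counts)
  } else {
    avg <- per_image[[1]]
    num <- vapply(avg, is.numeric, logical(1))
    for (cn in names(avg)[num]) {
      avg[[cn]] <- rowMeans(vapply(per_image, function(m) m[[cn]],
                                   numeric(nrow(avg))))
    }
    avg
  }
  if (bf1) met$bf1 <- c(rep(NA_real_, nrow(met) - 1L), mean(bfs))
  met
}

#' K-fold cross-validation
#'
#' Partitions the dataset with [make_folds()], then for each fold trains a
#' freshly initialized network on the remaining folds and evaluates on the
#' held-out fold. Emits one row per fold plus an `average` row (arithmetic
#' mean of the fold values), in the conventional benchmark-table format.
#'
#' @param pairs list of `image`/`mask` samples.
#' @param k fold count (default 5).
#' @param cfg a [train_config()].
#' @param network_cfg a [network_config()].
#' @param seed master seed: controls the partition, each fold's
#'   initialization, and shuffling; the same seed reproduces the table.
#' @param bf1 include mean boundary F1.
#' @param verbose print progress.
#' @return data.frame with columns `fold`, `dice`, `iou`, `precision`,
#'   `recall` (foreground metrics, micro-averaged within each fold), plus
#'   `bf1` when requested.
#' @export
cross_validate <- function(pairs, k = 5L, cfg, network_cfg, seed = 1L,
                           bf1 = FALSE, verbose = FALSE) {
  folds <- make_folds(length(pairs), k, seed = seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- pairs[folds$assignment != f]
    te <- pairs[folds$assignment == f]
    fold_seed <- child_seed(seed, f)
    fcfg <- cfg
    fcfg$seed <- fold_seed
    model <- build_network(network_cfg, seed = fold_seed)
    fit <- train_model(model, tr, cfg = fcfg, verbose = verbose)
    met <- evaluate_model(fit$model, te, bf1 = bf1)
    fg <- met$class != "mean" & met$class != "0"
    rows[[f]] <- data.frame(fold = f,
                            dice = mean(met$dice[fg]),
                            iou = mean(met$iou[fg]),
                            precision = mean(met$precision[fg]),
                            recall = mean(met$recall[fg]))
    if (bf1) rows[[f]]$bf1 <- met$bf1[nrow(met)]
    if (verbose) message(sprintf("fold %d: dice %.4f", f, rows[[f]]$dice))
  }
  tab <- do.call(rbind, rows)
  avg <- tab[1, , drop = FALSE]
  avg$fold <- "average"
  for (cn in names(tab)[-1]) avg[[cn]] <- mean(tab[[cn]])
  tab$fold <- as.character(tab$fold)
  rbind(tab, avg)
}

#' Synthetic ablation benchmark
#'
#' Trains the full network and its three single-ablation variants (frozen
#' stem removed, tri-atrous bottleneck removed, decoder fusion-aggregation
#' removed) on the same synthetic scenes and reports held-out foreground
#' Dice, paired over several seeds. This mirrors, in direction only, the
#' component-ablation analyses segmentation architectures are validated
#' with: each building block should contribute, so the full model's mean
#' Dice should not fall below any ablated variant's.
#'
#' The reduced preset (48x48 scenes, half-width network, 12 epochs) keeps a
#' full 4-variant x 3-seed sweep in the minutes range on one CPU; the full
#' preset uses 64x64 scenes and the default widths.
#'
#' @param seeds integer vector of master seeds; each seed generates its own
#'   scenes, initialization, and shuffling, shared by all four variants.
#' @param n_pairs scenes per seed (train + test).
#' @param n_test held-out scenes per seed.
#' @param preset `"reduced"` or `"full"`.
#' @param verbose print progress.
#' @return data.frame with one row per (seed, variant) and columns `seed`,
#'   `variant`, `dice`; attribute `means` holds the per-variant mean Dice.
#' @export
ablation_benchmark <- function(seeds = 1:3, n_pairs = 40L, n_test = 8L,
                               preset = c("reduced", "full"),
                               verbose = FALSE) {
  preset <- match.arg(preset)
  if (preset == "reduced") {
    side <- 48L
    # the bottleneck map is side/8 pixels wide, so the atrous dilations are
    # scaled down from the 256-input defaults to keep every kernel tap on
    # the feature map
    base <- list(input_height = side, input_width = side, stem_width = 8L,
                 encoder_widths = c(16L, 32L, 64L), tab_width = 32L,
                 tab_dilations = c(1L, 2L, 3L),
                 decoder_widths = c(32L, 16L, 8L))
    spec <- scene_spec(height = side, width = side,
                       instrument_width_range = c(4, 10),
                       instrument_length_range = c(24, 64))
    # two full phases of the step-decay schedule: ablation comparisons are
    # only meaningful once every variant has effectively converged
    epochs <- 24L
  } else {
    side <- 64L
    base <- list(input_height = side, input_width = side,
                 tab_dilations = c(1L, 2L, 3L))
    spec <- scene_spec(height = side, width = side,
                       instrument_width_range = c(5, 12),
                       instrument_length_range = c(30, 80))
    epochs <- 20L
  }
  variants <- list(
    full = list(),
    no_flfp = list(enable_flfp = FALSE),
    no_tab = list(enable_tab = FALSE),
    no_pspd_fusion = list(enable_pspd_fusion = FALSE))
  rows <- list()
  for (seed in seeds) {
    pairs <- generate_pairs(spec, n_pairs, seed = seed)
    tr <- pairs[seq_len(n_pairs - n_test)]
    te <- pairs[(n_pairs - n_test + 1L):n_pairs]
    for (v in names(variants)) {
      ncfg <- do.call(network_config, c(base, variants[[v]]))
      tcfg <- train_config(epochs = epochs, batch_size = 4L,
                           loss_kind = "weighted_ce", seed = seed)
      model <- build_network(ncfg, seed = seed)
      fit <- train_model(model, tr, cfg = tcfg)
      dice <- mean_foreground_dice(fit$model, te)
      rows[[length(rows) + 1L]] <- data.frame(seed = seed, variant = v,
                                              dice = dice)
      if (verbose) message(sprintf("seed %d %-15s dice %.4f", seed, v, dice))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "means") <- tapply(out$dice, out$variant, mean)
  out
}
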