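#' Network configuration
#'
#' Collects every architectural free parameter of the segmentation network.
#' The default plan (stem 16; encoder 32/64/128; tri-atrous bottleneck at
#' dilations 2/4/6 with 64-channel streams; decoder 64/32/16) lands the
#' trainable parameter count near 1.2 million, inside the 1.5 million budget
#' the architecture is designed for.
#'
#' @param input_height,input_width input resolution in pixels; each must be
#'   divisible by 8 (three stride-2 encoder reductions).
#' @param input_channels image channels (3 for RGB).
#' @param num_classes number of segmentation classes (>= 2, background is
#'   class 0).
#' @param stem_width channels of the learnable stem branch.
#' @param encoder_widths channel counts of the three strided encoder stages.
#' @param tab_dilations strictly increasing dilation rates of the three
#'   parallel atrous streams in the bottleneck.
#' @param tab_width channels per atrous stream.
#' @param decoder_widths channel counts of the three decoder stages.
#' @param pspd_dilation dilation of the mildly dilated decoder branch.
#' @param enable_flfp,enable_tab,enable_pspd_fusion ablation switches: when
#'   `FALSE` the corresponding sub-graph is replaced by a plain convolution
#'   of matching width (for `enable_pspd_fusion = FALSE`, the decoder's skip
#'   fusion and the dilated/standard aggregation are removed together, since
#'   the skip paths only exist to feed that fusion).
#' @return object of class `network_config`.
#' @export
network_config <- function(input_height = 256L, input_width = 256L,
                           input_channels = 3L, num_classes = 2L,
                           stem_width = 16L,
                           encoder_widths = c(32L, 64L, 128L),
                           tab_dilations = c(2L, 4L, 6L),
                           tab_width = 64L,
                           decoder_widths = c(64L, 32L, 16L),
                           pspd_dilation = 2L,
                           enable_flfp = TRUE, enable_tab = TRUE,
                           enable_pspd_fusion = TRUE) {
  cfg <- list(input_height = as.integer(input_height),
              input_width = as.integer(input_width),
              input_channels = as.integer(input_channels),
              num_classes = as.integer(num_classes),
              stem_width = as.integer(stem_width),
              encoder_widths = as.integer(encoder_widths),
              tab_dilations = as.integer(tab_dilations),
              tab_width = as.integer(tab_width),
              decoder_widths = as.integer(decoder_widths),
              pspd_dilation = as.integer(pspd_dilation),
              enable_flfp = isTRUE(enable_flfp),
              enable_tab = isTRUE(enable_tab),
              enable_pspd_fusion = isTRUE(enable_pspd_fusion))
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  if (cfg$input_height %% 8L != 0L || cfg$input_width %% 8L != 0L) {
    stopf("input size %dx%d not divisible by 8", cfg$input_height, cfg$input_width)
  }
  if (cfg$num_classes < 2L) stopf("num_classes must be >= 2")
  widths <- c(cfg$stem_width, cfg$encoder_widths, cfg$tab_width, cfg$decoder_widths)
  if (any(widths <= 0L)) stopf("all channel widths must be positive")
  if (length(cfg$encoder_widths) != 3L || length(cfg$decoder_widths) != 3L) {
    stopf("encoder_widths and decoder_widths must each have length 3")
  }
  if (length(cfg$tab_dilations) != 3L || any(diff(cfg$tab_dilations) <= 0L) ||
      any(cfg$tab_dilations < 1L)) {
    stopf("tab_dilations must be 3 strictly increasing positive integers")
  }
  if (cfg$pspd_dilation < 1L) stopf("pspd_dilation must be >= 1")
  invisible(cfg)
}

#' Build the segmentation network
#'
#' Assembles the full model graph: the frozen/learnable stem (a learnable
#' two-block branch in parallel with the frozen-filter unit), three stride-2
#' encoder stages, the tri-atrous bottleneck, and the structure-preserving
#' decoder whose three upsampling stages fuse projected encoder features and
#' aggregate a dilated with a standard convolution branch, ending in a 1x1
#' classifier head followed by a per-pixel softmax.
#'
#' Frozen kernels live outside the trainable parameter set: the optimizer
#' never sees them and [count_trainable_params()] never counts them.
#'
#' @param cfg a [network_config()].
#' @param seed optional integer; when given, weight initialization
#'   (He-uniform) is reproducible.
#' @param max_params optional budget; if the built model exceeds it, an
#'   error is raised.
#' @return object of class `seg_model`.
#' @export
build_network <- function(cfg, seed = NULL, max_params = NULL) {
  validate_network_config(cfg)
  model <- with_seed(seed, build_network_graph(cfg))
  if (!is.null(max_params) && count_trainable_params(model) > max_params) {
    stopf("model has %d trainable parameters, over the budget of %d",
          count_trainable_params(model), as.integer(max_params))
  }
  model
}

build_network_graph <- function(cfg) {
  params <- list()
  decay <- character(0)
  state <- list()
  ops <- list()

  add_op <- function(op) ops[[length(ops) + 1L]] <<- op

  conv <- function(name, input, cin, cout, k = 3L, stride = 1L, dil = 1L) {
    wn <- paste0(name, ".w"); bn_ <- paste0(name, ".b")
    params[[wn]] <<- he_uniform(c(k, k, cin, cout), k * k * cin)
    params[[bn_]] <<- numeric(cout)
    decay <<- c(decay, wn)
    add_op(list(name = name, kind = "conv", inputs = input, w = wn, b = bn_,
                stride = stride, dil = dil))
    name
  }
  tconv <- function(name, input, cin, cout) {
    wn <- paste0(name, ".w"); bn_ <- paste0(name, ".b")
    params[[wn]] <<- he_uniform(c(4L, 4L, cout, cin), 4L * 4L * cin)
    params[[bn_]] <<- numeric(cout)
    decay <<- c(decay, wn)
    add_op(list(name = name, kind = "tconv", inputs = input, w = wn, b = bn_))
    name
  }
  bn <- function(name, input, c) {
    gn <- paste0(name, ".gamma"); be <- paste0(name, ".beta")
    params[[gn]] <<- rep(1, c)
    params[[be]] <<- numeric(c)
    state[[name]] <<- list(mean = numeric(c), var = rep(1, c))
    add_op(list(name = name, kind = "bn", inputs = input, gamma = gn, beta = be))
    name
  }
  relu <- function(name, input) {
    add_op(list(name = name, kind = "relu", inputs = input)); name
  }
  frozen <- function(name, input) {
    add_op(list(name = name, kind = "frozen", inputs = input)); name
  }
  concat <- function(name, inputs) {
    add_op(list(name = name, kind = "concat", inputs = inputs)); name
  }
  ewadd <- function(name, a, b) {
    add_op(list(name = name, kind = "add", inputs = c(a, b))); name
  }
  cbr <- function(name, input, cin, cout, k = 3L, stride = 1L, dil = 1L) {
    relu(paste0(name, ".relu"),
         bn(paste0(name, ".bn"),
            conv(name, input, cin, cout, k, stride, dil), cout))
  }

  sw <- cfg$stem_width; ew <- cfg$encoder_widths
  tw <- cfg$tab_width; dw <- cfg$decoder_widths
  cin <- cfg$input_channels

  ## --- stem: learnable branch + frozen filter unit, fused and squeezed ---
  learn <- cbr("stem.conv2", cbr("stem.conv1", "x", cin, sw), sw, sw)
  if (cfg$enable_flfp) {
    ffu <- frozen("stem.mffl",
                  relu("stem.ffu_relu",
                       conv("stem.ffu_pw", "x", cin, sw, k = 1L)))
    fused <- concat("stem.concat", c(learn, ffu)) # sw + 3*sw channels
    stem_out <- cbr("stem.squeeze", fused, 4L * sw, sw, k = 1L)
  } else {
    # ablation: learnable branch only, same squeeze width
    stem_out <- cbr("stem.squeeze", learn, sw, sw, k = 1L)
  }

  ## --- encoder: three [stride-2 conv -> conv+BN+ReLU] stages -------------
  enc_in <- c(sw, ew[1], ew[2])
  enc_out <- stem_out
  enc_feats <- character(3)
  for (s in 1:3) {
    enc_feats[s] <- enc_out # pre-stride features of stage s
    st <- conv(sprintf("enc%d.down", s), enc_out, enc_in[s], ew[s], stride = 2L)
    enc_out <- cbr(sprintf("enc%d.conv", s), st, ew[s], ew[s])
  }

  ## --- tri-atrous bottleneck ---------------------------------------------
  if (cfg$enable_tab) {
    streams <- character(3)
    for (i in 1:3) {
      at <- conv(sprintf("tab.atrous%d", i), enc_out, ew[3], tw,
                 dil = cfg$tab_dilations[i])
      streams[i] <- conv(sprintf("tab.pw%d", i), at, tw, tw, k = 1L)
    }
    tab_cat <- concat("tab.concat", streams)
    bott <- cbr("tab.fuse", tab_cat, 3L * tw, ew[3])
  } else {
    bott <- cbr("tab.fuse", enc_out, ew[3], ew[3])
  }

  ## --- decoder: upsample, fuse skip, aggregate dilated + standard --------
  # fusion sources: C2 <- encoder stage-3 input, C3 <- stage-2 input,
  # C4 <- stem output (= stage-1 input)
  skip_src <- c(enc_feats[3], enc_feats[2], enc_feats[1])
  skip_ch <- c(enc_in[3], enc_in[2], enc_in[1])
  dec_in <- c(ew[3], dw[1], dw[2])
  node <- bott
  for (s in 1:3) {
    up <- tconv(sprintf("dec%d.up", s), node, dec_in[s], dw[s])
    if (cfg$enable_pspd_fusion) {
      lsp <- bn(sprintf("dec%d.lsp.bn", s),
                conv(sprintf("dec%d.lsp", s), skip_src[s], skip_ch[s], dw[s],
                     k = 1L), dw[s])
      fus <- concat(sprintf("dec%d.concat", s), c(up, lsp))
      di <- conv(sprintf("dec%d.di", s), fus, 2L * dw[s], dw[s],
                 dil = cfg$pspd_dilation)
      stdc <- conv(sprintf("dec%d.std", s), fus, 2L * dw[s], dw[s])
      agg <- ewadd(sprintf("dec%d.add", s), di, stdc)
      node <- cbr(sprintf("dec%d.out", s), agg, dw[s], dw[s])
    } else {
      node <- cbr(sprintf("dec%d.out", s), up, dw[s], dw[s])
    }
  }

  ## --- classifier head ----------------------------------------------------
  head <- conv("head", node, dw[3], cfg$num_classes, k = 1L)

  model <- list(cfg = cfg, graph = ops, params = params,
                decay_params = decay, state = state,
                frozen = if (cfg$enable_flfp) make_frozen_bank() else NULL,
                output_node = head)
  class(model) <- "seg_model"
  model
}

#' Count trainable parameters
#'
#' Sums the element counts of every learnable convolution weight, bias, and
#' batch-normalization scale/shift. The frozen kernel bank is excluded: it
#' is fixed at construction and receives no gradient.
#'
#' @param model a `seg_model`.
#' @return nonnegative integer.
#' @export
count_trainable_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("seg_model: %dx%dx%d -> %d classes, %d ops, %s trainable parameters%s\n",
              cfg$input_height, cfg$input_width, cfg$input_channels,
              cfg$num_classes, length(x$graph),
              format(count_trainable_params(x), big.mark = ","),
              if (is.null(x$frozen)) "" else " (+3 frozen kernels)"))
  invisible(x)
}

#' Run the network in inference mode
#'
#' @param model a `seg_model`.
#' @param batch numeric array `H x W x C` (single image) or `H x W x C x N`,
#'   values in `[0, 1]`.
#' @return per-pixel class probabilities, `H x W x K x N` (or `H x W x K`
#'   for a single image); each pixel's probabilities sum to 1.
#' @export
forward <- function(model, batch) {
  d <- dim(batch)
  squeeze <- FALSE
  if (length(d) == 3L) { dim(batch) <- c(d, 1L); squeeze <- TRUE; d <- dim(batch) }
  cfg <- model$cfg
  if (length(d) != 4L || d[1] != cfg$input_height || d[2] != cfg$input_width ||
      d[3] != cfg$input_channels) {
    stopf("batch shape (%s) does not match the model input %dx%dx%d",
          paste(d, collapse = "x"), cfg$input_height, cfg$input_width,
          cfg$input_channels)
  }
  if (!all(is.finite(batch))) stopf("batch contains non-finite values")
  fw <- net_forward(model, batch, training = FALSE, keep_cache = FALSE)
  probs <- softmax_channels(fw$logits)
  if (squeeze) dim(probs) <- dim(probs)[1:3]
  probs
}

#' Per-pixel classification: probabilities to label mask
#'
#' Argmax over the class dimension; ties break toward the lowest class
#' index, so an exactly uniform pixel is labelled background.
#'
#' @param probs `H x W x K` or `H x W x K x N` probability array.
#' @return integer label array `H x W` (or `H x W x N`), 0-based labels.
#' @export
predict_mask <- function(probs) {
  d <- dim(probs)
  squeeze <- FALSE
  if (length(d) == 3L) { dim(probs) <- c(d, 1L); squeeze <- TRUE; d <- dim(probs) }
  K <- d[3]
  m <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = K)
  lab <- max.col(m, ties.method = "first") - 1L
  out <- array(as.integer(lab), dim = c(d[1], d[2], d[4]))
  if (squeeze) dim(out) <- d[1:2]
  out
}

#' Segment a batch of images
#'
#' Convenience wrapper: [forward()] followed by [predict_mask()].
#' @inheritParams forward
#' @return integer label mask(s), 0-based.
#' @export
segment <- function(model, batch) {
  predict_mask(forward(model, batch))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the configuration, all trainable
#' parameters, batch-normalization running statistics, and the frozen
#' kernel bank.
#'
#' @param model a `seg_model`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  class(model$cfg) <- "network_config"
  class(model) <- "seg_model"
  if (!is.null(model$frozen)) class(model$frozen) <- "frozen_kernel_bank"
  model
}

#' Read / write a network configuration as YAML
#'
#' @param path YAML file with one key per [network_config()] argument;
#'   missing keys take the defaults.
#' @export
read_network_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(network_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown network config keys: %s", paste(bad, collapse = ", "))
  do.call(network_config, vals)
}

#' @rdname read_network_config
#' @param cfg a `network_config`.
#' @export
write_network_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
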