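# Internal layer primitives and the static-graph executor.
#
# A model's graph is an ordered list of ops. Each op names its input node(s)
# and its parameters; node values are cached by op name during the forward
# pass so the reverse sweep can replay the graph. Supported kinds:
# conv, tconv, bn, relu, concat, add, frozen.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# broadcast a per-channel vector over an (H, W, C, N) array
bc_channel <- function(v, d) {
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}

# per-channel sums over an (H, W, C, N) array
channel_sums <- function(x, d) {
  .rowSums(matrix(.colSums(x, d[1] * d[2], d[3] * d[4]), nrow = d[3]),
           d[3], d[4])
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

bn_forward <- function(x, gamma, beta, st, training) {
  d <- dim(x)
  n_el <- d[1] * d[2] * d[4]
  if (training) {
    mu <- channel_sums(x, d) / n_el
    xc <- x - bc_channel(mu, d)
    v <- channel_sums(xc * xc, d) / n_el
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * bc_channel(invstd, d)
    dim(xhat) <- d
    y <- xhat * bc_channel(gamma, d) + bc_channel(beta, d)
    dim(y) <- d
    st$mean <- (1 - BN_MOMENTUM) * st$mean + BN_MOMENTUM * mu
    st$var <- (1 - BN_MOMENTUM) * st$var + BN_MOMENTUM * v
    list(y = y, cache = list(xhat = xhat, invstd = invstd, n_el = n_el),
         state = st)
  } else {
    invstd <- 1 / sqrt(st$var + BN_EPS)
    y <- (x - bc_channel(st$mean, d)) * bc_channel(invstd * gamma, d) +
      bc_channel(beta, d)
    dim(y) <- d
    list(y = y, cache = NULL, state = st)
  }
}

bn_backward <- function(dy, gamma, cache) {
  d <- dim(dy)
  xhat <- cache$xhat
  n_el <- cache$n_el
  dgamma <- channel_sums(dy * xhat, d)
  dbeta <- channel_sums(dy, d)
  dxhat <- dy * bc_channel(gamma, d)
  dx <- bc_channel(cache$invstd, d) *
    (dxhat - bc_channel(dbeta * (1 / n_el) * gamma, d) -
       xhat * bc_channel(dgamma * (1 / n_el) * gamma, d))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

concat_channels <- function(pieces) {
  d1 <- dim(pieces[[1]])
  cs <- vapply(pieces, function(p) dim(p)[3], integer(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (p in pieces) {
    cp <- dim(p)[3]
    out[, , (at + 1L):(at + cp), ] <- p
    at <- at + cp
  }
  out
}

# Forward sweep. Returns logits plus (optionally) all cached node values.
net_forward <- function(model, x, training = FALSE, keep_cache = training) {
  acts <- new.env(parent = emptyenv())
  assign("x", x, envir = acts)
  bn_caches <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  p <- model$params
  for (op in model$graph) {
    inp <- if (op$kind %in% c("concat", "add")) {
      lapply(op$inputs, function(nm) get(nm, envir = acts))
    } else {
      get(op$inputs[1], envir = acts)
    }
    y <- switch(op$kind,
      conv = .cpp_conv2d_fw(inp, p[[op$w]], p[[op$b]],
                            as.integer(op$stride), as.integer(op$dil), 0L),
      tconv = .cpp_tconv2d_fw(inp, p[[op$w]], p[[op$b]]),
      frozen = .cpp_frozen_fw(inp, model$frozen$kernels),
      relu = { z <- inp * (inp > 0); dim(z) <- dim(inp); z },
      bn = {
        r <- bn_forward(inp, p[[op$gamma]], p[[op$beta]],
                        model$state[[op$name]], training)
        if (training) model$state[[op$name]] <- r$state
        if (keep_cache) assign(op$name, r$cache, envir = bn_caches)
        r$y
      },
      concat = concat_channels(inp),
      add = inp[[1]] + inp[[2]],
      stopf("unknown op kind '%s'", op$kind))
    assign(op$name, y, envir = acts)
  }
  logits <- get(model$output_node, envir = acts)
  list(logits = logits, acts = if (keep_cache) acts else NULL,
       bn_caches = bn_caches, model = model)
}

# Reverse sweep: gradient of the scalar loss w.r.t. every trainable
# parameter, given d(loss)/d(logits). Frozen kernels receive no gradient.
net_backward <- function(model, fw, dlogits) {
  grads <- new.env(parent = emptyenv())
  pgrads <- list()
  assign(model$output_node, dlogits, envir = grads)
  acts <- fw$acts
  p <- model$params
  acc <- function(nm, g) {
    cur <- if (exists(nm, envir = grads, inherits = FALSE)) get(nm, envir = grads) else NULL
    assign(nm, if (is.null(cur)) g else cur + g, envir = grads)
  }
  for (op in rev(model$graph)) {
    if (!exists(op$name, envir = grads, inherits = FALSE)) next
    dy <- get(op$name, envir = grads)
    switch(op$kind,
      conv = {
        r <- .cpp_conv2d_bw(get(op$inputs[1], envir = acts), p[[op$w]], dy,
                            as.integer(op$stride), as.integer(op$dil), 0L)
        acc(op$inputs[1], r$dx)
        pgrads[[op$w]] <- r$dw
        pgrads[[op$b]] <- r$db
      },
      tconv = {
        r <- .cpp_tconv2d_bw(get(op$inputs[1], envir = acts), p[[op$w]], dy)
        acc(op$inputs[1], r$dx)
        pgrads[[op$w]] <- r$dw
        pgrads[[op$b]] <- r$db
      },
      frozen = {
        xin <- get(op$inputs[1], envir = acts)
        d <- dim(xin)
        acc(op$inputs[1],
            .cpp_frozen_bw(dy, model$frozen$kernels, d[1], d[2], d[3], d[4]))
      },
      relu = {
        xin <- get(op$inputs[1], envir = acts)
        g <- dy * (xin > 0); dim(g) <- dim(dy)
        acc(op$inputs[1], g)
      },
      bn = {
        r <- bn_backward(dy, p[[op$gamma]], get(op$name, envir = fw$bn_caches))
        acc(op$inputs[1], r$dx)
        pgrads[[op$gamma]] <- r$dgamma
        pgrads[[op$beta]] <- r$dbeta
      },
      concat = {
        at <- 0L
        for (nm in op$inputs) {
          cp <- dim(get(nm, envir = acts))[3]
          acc(nm, dy[, , (at + 1L):(at + cp), , drop = FALSE])
          at <- at + cp
        }
      },
      add = {
        acc(op$inputs[1], dy)
        acc(op$inputs[2], dy)
      })
  }
  pgrads
}

# Per-pixel softmax over the class dimension of (H, W, K, N) logits.
softmax_channels <- function(logits) {
  d <- dim(logits)
  K <- d[3]
  mx <- logits[, , 1, , drop = FALSE]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, logits[, , k, , drop = FALSE])
  probs <- array(0, dim = d)
  s <- array(0, dim = dim(mx))
  for (k in seq_len(K)) {
    e <- exp(logits[, , k, , drop = FALSE] - mx)
    probs[, , k, ] <- e
    s <- s + e
  }
  for (k in seq_len(K)) probs[, , k, ] <- probs[, , k, , drop = FALSE] / s
  probs
}
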