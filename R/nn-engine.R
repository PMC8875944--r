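# Compact CPU engine executing architecture_spec graphs. Tensors are R
# arrays in (H, W, C, N) layout; flat features are (width x N) matrices.
# Convolutions and batch norm run in C++ (src/convops.cpp) with per-image
# im2col workspaces and BLAS gemm; the backward pass recomputes patches
# instead of caching them, which bounds peak memory at the cost of ~30%
# extra convolution work.

bn_eps <- 1e-5
bn_momentum <- 0.9

init_params_for <- function(layer, in_shape, n_next_relu) {
  if (layer$kind == "conv2d") {
    fan_in <- prod(layer$kernel) * in_shape[3]
    sd <- sqrt(2 / fan_in)  # He initialization for ReLU stacks
    list(W = array(rnorm(fan_in * layer$filters, sd = sd),
                   c(layer$kernel[1], layer$kernel[2], in_shape[3],
                     layer$filters)),
         b = numeric(layer$filters))
  } else if (layer$kind == "dense") {
    fan_in <- in_shape[1]
    lim <- sqrt(6 / (fan_in + layer$units))  # Glorot for the softmax head
    sd <- sqrt(2 / fan_in)
    W <- if (n_next_relu)
      matrix(rnorm(layer$units * fan_in, sd = sd), layer$units, fan_in)
    else matrix(runif(layer$units * fan_in, -lim, lim), layer$units, fan_in)
    list(W = W, b = numeric(layer$units))
  } else if (layer$kind == "batchnorm") {
    ch <- if (length(in_shape) == 1L) in_shape else in_shape[3]
    list(gamma = rep(1, ch), beta = numeric(ch))
  } else NULL
}

# Compile an architecture_spec into an executable model: instantiated
# parameter tensors, batch-norm running statistics, and the layer walk.
compile_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture_spec"))
  params <- list(); state <- list()
  with_seed(seed, {
    build <- function(layers, prefix) {
      shape <- arch$input_shape
      if (identical(prefix, "H")) shape <- attr(layers, "in_width")
      for (i in seq_along(layers)) {
        layer <- layers[[i]]
        nm <- sprintf("%s%02d", prefix, i)
        nxt <- i < length(layers) && layers[[i + 1L]]$kind == "activation" &&
          layers[[i + 1L]]$activation == "relu"
        p <- init_params_for(layer, shape, nxt)
        if (!is.null(p)) params[[nm]] <<- p
        if (layer$kind == "batchnorm") {
          ch <- if (length(shape) == 1L) shape else shape[3]
          state[[nm]] <<- list(mean = numeric(ch), var = rep(1, ch),
                               count = 0L)
        }
        shape <- layer_out_shape(layer, shape)
      }
      shape
    }
    widths <- numeric(0)
    for (b in seq_along(arch$branches))
      widths[b] <- build(arch$branches[[b]], sprintf("B%d_", b))[1]
    if (!is.null(arch$fusion_head)) {
      head <- arch$fusion_head[-1L]
      attr(head, "in_width") <- sum(widths)
      build(head, "H")
    }
  })
  structure(list(arch = arch, params = params, state = state),
            class = "fdc_compiled")
}

n_engine_params <- function(model) {
  sum(vapply(model$params,
             function(p) sum(vapply(p, length, 0L)), 0))
}

# ---- single-layer forward/backward ----------------------------------------

layer_forward <- function(layer, nm, x, params, state, training,
                          bn_batch_stats = training) {
  cache <- list()
  new_state <- NULL
  y <- switch(layer$kind,
    conv2d = {
      p <- params[[nm]]
      pad <- conv_pad(layer)
      y <- conv2d_forward(x, dim(x), p$W, dim(p$W), p$b, pad[1], pad[2],
                          layer$activation == "relu")
      cache <- list(x = x, out = y)
      y
    },
    batchnorm = {
      p <- params[[nm]]
      dims <- dim(x)
      if (bn_batch_stats) {
        res <- bn_forward(x, dims, p$gamma, p$beta, bn_eps)
        st <- state[[nm]]
        # cumulative average while warming up, exponential after: the
        # running statistics are usable for validation from the first epoch
        mom <- min(bn_momentum, st$count / (st$count + 1))
        new_state <- list(mean = mom * st$mean + (1 - mom) * res$mean,
                          var = mom * st$var + (1 - mom) * res$var,
                          count = st$count + 1L)
        cache <- list(xhat = res$xhat, inv = res$inv, dims = dims)
        res$y
      } else {
        st <- state[[nm]]
        bn_eval(x, dims, p$gamma, p$beta, st$mean, st$var, bn_eps)
      }
    },
    maxpool2d = {
      res <- maxpool_forward(x, dim(x), layer$pool[1], layer$pool[2],
                             layer$padding == "same")
      cache <- list(argmax = res$argmax, in_dims = dim(x))
      res$out
    },
    activation = {
      if (layer$activation == "relu") {
        y <- pmax(x, 0)
        cache <- list(out = y)
        y
      } else if (layer$activation == "softmax") {
        z <- if (is.matrix(x)) x else matrix(x, ncol = ncol(x))
        z <- sweep(z, 2, apply(z, 2, max))
        e <- exp(z)
        p <- sweep(e, 2, colSums(e), "/")
        cache <- list(logits = x)
        p
      } else x
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- runif(length(x)) >= layer$rate
        y <- x * mask / (1 - layer$rate)
        if (!is.null(dim(x))) dim(y) <- dim(x)
        cache <- list(mask = mask)
        y
      } else x
    },
    flatten = {
      cache <- list(in_dims = dim(x))
      matrix(x, prod(dim(x)[1:3]), dim(x)[4])
    },
    dense = {
      p <- params[[nm]]
      cache <- list(x = x)
      p$W %*% x + p$b
    },
    global_avg_pool = {
      dims <- dim(x)
      cache <- list(in_dims = dims)
      matrix(colMeans(matrix(x, dims[1] * dims[2], dims[3] * dims[4])),
             dims[3], dims[4])
    },
    stop("engine: unsupported layer: ", layer$kind))
  list(y = y, cache = cache, state = new_state)
}

layer_backward <- function(layer, nm, dy, cache, params, need_dx = TRUE) {
  grads <- NULL
  dx <- switch(layer$kind,
    conv2d = {
      p <- params[[nm]]
      pad <- conv_pad(layer)
      res <- conv2d_backward(cache$x, dim(cache$x), p$W, dim(p$W), dy,
                             cache$out, pad[1], pad[2],
                             layer$activation == "relu", need_dx)
      grads <- list(W = res$dW + if (layer$l2 > 0) 2 * layer$l2 * p$W else 0,
                    b = res$db)
      res$dx
    },
    batchnorm = {
      p <- params[[nm]]
      res <- bn_backward(dy, cache$xhat, cache$dims, p$gamma, cache$inv)
      grads <- list(gamma = res$dgamma, beta = res$dbeta)
      res$dx
    },
    maxpool2d = maxpool_backward(dy, cache$argmax, cache$in_dims),
    activation = {
      if (layer$activation == "relu") dy * (cache$out > 0) else dy
    },
    dropout = {
      if (!is.null(cache$mask)) {
        dx <- dy * cache$mask / (1 - layer$rate)
        if (!is.null(dim(dy))) dim(dx) <- dim(dy)
        dx
      } else dy
    },
    flatten = array(dy, cache$in_dims),
    dense = {
      p <- params[[nm]]
      grads <- list(W = dy %*% t(cache$x), b = rowSums(dy))
      crossprod(p$W, dy)
    },
    global_avg_pool = {
      dims <- cache$in_dims
      array(rep(as.vector(dy), each = dims[1] * dims[2]) /
              (dims[1] * dims[2]), dims)
    },
    stop("engine backward: unsupported layer: ", layer$kind))
  list(dx = dx, grads = grads)
}

# ---- whole-model forward/backward -----------------------------------------

# x: (H, W, C, N) array. Returns class probabilities (K x N) and, when
# training, the caches needed for the backward pass. bn_batch_stats governs
# whether batch norm normalizes by batch statistics (and updates the running
# ones) or by the stored running statistics.
engine_forward <- function(model, x, training = FALSE, keep_cache = training,
                           bn_batch_stats = training) {
  arch <- model$arch
  caches <- list()
  state <- model$state
  run <- function(layers, prefix, input) {
    cc <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      nm <- sprintf("%s%02d", prefix, i)
      res <- layer_forward(layers[[i]], nm, input, model$params, state,
                           training, bn_batch_stats)
      input <- res$y
      if (keep_cache) cc[[i]] <- res$cache
      if (!is.null(res$state)) state[[nm]] <<- res$state
    }
    if (keep_cache) caches[[prefix]] <<- cc
    input
  }
  outs <- vector("list", length(arch$branches))
  for (b in seq_along(arch$branches))
    outs[[b]] <- run(arch$branches[[b]], sprintf("B%d_", b), x)
  y <- if (is.null(arch$fusion_head)) outs[[1L]]
       else run(arch$fusion_head[-1L], "H", do.call(rbind, outs))
  list(probs = y, caches = caches, state = state,
       branch_widths = vapply(outs, nrow, 0L))
}

# Cross-entropy gradients for every parameter tensor. labels: integers 1..K.
engine_backward <- function(model, fwd, labels) {
  arch <- model$arch
  probs <- fwd$probs
  n <- ncol(probs)
  Y <- matrix(0, nrow(probs), n)
  Y[cbind(labels, seq_len(n))] <- 1
  dz <- (probs - Y) / n   # gradient at the softmax layer's input
  grads <- list()
  back <- function(layers, prefix, dy, stop_at_input = FALSE) {
    cc <- fwd$caches[[prefix]]
    for (i in rev(seq_along(layers))) {
      layer <- layers[[i]]
      if (layer$kind == "activation" && layer$activation == "softmax")
        next  # combined with the cross-entropy gradient already in dy
      nm <- sprintf("%s%02d", prefix, i)
      # input gradients are never consumed at a branch's first layer
      res <- layer_backward(layer, nm, dy, cc[[i]], model$params,
                            need_dx = !(stop_at_input && i == 1L))
      if (!is.null(res$grads)) grads[[nm]] <<- res$grads
      dy <- res$dx
    }
    dy
  }
  if (is.null(arch$fusion_head)) {
    back(arch$branches[[1L]], "B1_", dz, stop_at_input = TRUE)
  } else {
    dfeat <- back(arch$fusion_head[-1L], "H", dz)
    offsets <- cumsum(c(0L, fwd$branch_widths))
    for (b in seq_along(arch$branches)) {
      rows <- (offsets[b] + 1L):offsets[b + 1L]
      back(arch$branches[[b]], sprintf("B%d_", b),
           dfeat[rows, , drop = FALSE], stop_at_input = TRUE)
    }
  }
  grads
}

engine_loss <- function(model, probs, labels) {
  ce <- -mean(log(pmax(probs[cbind(labels, seq_len(ncol(probs)))], 1e-12)))
  pen <- 0
  walk <- function(layers, prefix) {
    for (i in seq_along(layers)) {
      if (layers[[i]]$kind %in% c("conv2d", "dense") && layers[[i]]$l2 > 0)
        pen <<- pen + layers[[i]]$l2 *
          sum(model$params[[sprintf("%s%02d", prefix, i)]]$W^2)
    }
  }
  for (b in seq_along(model$arch$branches))
    walk(model$arch$branches[[b]], sprintf("B%d_", b))
  if (!is.null(model$arch$fusion_head)) walk(model$arch$fusion_head[-1L], "H")
  ce + pen
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0,
       m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"))
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    for (k in names(grads[[nm]])) {
      g <- grads[[nm]][[k]]
      opt$m[[nm]][[k]] <- beta1 * opt$m[[nm]][[k]] + (1 - beta1) * g
      opt$v[[nm]][[k]] <- beta2 * opt$v[[nm]][[k]] + (1 - beta2) * g * g
      params[[nm]][[k]] <- params[[nm]][[k]] -
        lr * (opt$m[[nm]][[k]] / corr1) /
          (sqrt(opt$v[[nm]][[k]] / corr2) + eps)
    }
  }
  list(params = params, opt = opt)
}

# Re-estimate batch-norm running statistics under the current weights:
# a stats-only sweep (no dropout, no caches) with the cumulative-average
# schedule, so evaluation reflects the model actually being trained.
# A no-op for architectures without batch norm.
engine_recalibrate_bn <- function(model, x, chunk = 16L) {
  if (length(model$state) == 0L) return(model)
  for (nm in names(model$state)) model$state[[nm]]$count <- 0L
  n <- dim(x)[4]
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    fwd <- engine_forward(model, x[, , , idx, drop = FALSE],
                          training = FALSE, keep_cache = FALSE,
                          bn_batch_stats = TRUE)
    model$state <- fwd$state
  }
  model
}

# eval-mode forward in chunks to bound memory
engine_predict_probs <- function(model, x, chunk = 32L) {
  n <- dim(x)[4]
  out <- NULL
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    p <- engine_forward(model, x[, , , idx, drop = FALSE],
                        training = FALSE, keep_cache = FALSE)$probs
    out <- cbind(out, p)
  }
  out
}
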