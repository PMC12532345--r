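# Minimal feed-forward neural network engine: 1D convolution, max pooling,
# dense layers, ReLU/tanh, manual backprop and Adam. Batched inputs are
# arrays [batch, channels, depth] for conv layers and matrices
# [batch, features] for dense layers; all heavy lifting is BLAS matrix
# multiplication via im2col.

# Glorot init for dense layers: sd^2 = 2/(fan_in + fan_out). Fan-in-only
# scaling is pathological here — the critic head's first layer has
# fan_in = 2, fan_out = 500, and He-by-fan-in (sd 1) amplifies the backward
# pass ~250x into the embedding/action inputs, collapsing the trunk.
nn_init_dense <- function(n_in, n_out, init_scale = NULL) {
  if (is.null(init_scale)) {
    s <- sqrt(2 / (n_in + n_out))
    w <- matrix(stats::rnorm(n_in * n_out, 0, s), n_in, n_out)
  } else {
    w <- matrix(stats::runif(n_in * n_out, -init_scale, init_scale),
                n_in, n_out)
  }
  list(type = "dense", W = w, b = numeric(n_out))
}

nn_init_conv1d <- function(in_ch, out_ch, kernel) {
  fan_in <- in_ch * kernel
  # stored as [in_ch, kernel, out_ch] so matrix(W, in_ch*kernel, out_ch)
  # matches the im2col column order (channel fastest within each tap)
  w <- array(stats::rnorm(in_ch * kernel * out_ch, 0, sqrt(2 / fan_in)),
             dim = c(in_ch, kernel, out_ch))
  list(type = "conv1d", W = w, b = numeric(out_ch), kernel = kernel,
       in_ch = in_ch, out_ch = out_ch)
}

# build a network from a list of layer specs; specs with learnable
# parameters are initialized here (call set.seed beforehand for
# reproducibility)
nn_network <- function(specs) {
  layers <- lapply(specs, function(s) {
    switch(s$type,
      dense = nn_init_dense(s$n_in, s$n_out, s$init_scale),
      conv1d = nn_init_conv1d(s$in_ch, s$out_ch, s$kernel),
      relu = list(type = "relu"),
      tanh = list(type = "tanh"),
      maxpool = list(type = "maxpool", k = if (is.null(s$k)) 2L else s$k),
      flatten = list(type = "flatten"),
      stop("unknown layer type: ", s$type)
    )
  })
  structure(list(layers = layers), class = "nn_network")
}

conv1d_forward <- function(layer, x) {
  d <- dim(x)  # B, C, D
  k <- layer$kernel
  l_out <- d[3] - k + 1L
  x2 <- .Call(C_im2col, x, as.integer(d), as.integer(k))
  w2 <- matrix(layer$W, d[2] * k, layer$out_ch)
  y2 <- .Call(C_add_bias, x2 %*% w2, layer$b)
  y <- .Call(C_blc_to_bcl, y2, as.integer(c(d[1], layer$out_ch, l_out)))
  list(out = y, cache = list(x2 = x2, dims = d, l_out = l_out))
}

conv1d_backward <- function(layer, cache, dy, param_grads = TRUE) {
  d <- cache$dims
  k <- layer$kernel
  l_out <- cache$l_out
  dy2 <- .Call(C_bcl_to_blc, dy, as.integer(c(d[1], layer$out_ch, l_out)))
  dw2 <- if (param_grads) crossprod(cache$x2, dy2)
  db <- if (param_grads) colSums(dy2)
  w2 <- matrix(layer$W, d[2] * k, layer$out_ch)
  dx2 <- tcrossprod(dy2, w2)          # = dy2 %*% t(w2)
  dx <- .Call(C_col2im, dx2, as.integer(d), as.integer(k))
  list(dW = if (param_grads) array(dw2, dim = dim(layer$W)), db = db,
       dx = dx)
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  y <- .Call(C_maxpool2, x, as.integer(d))
  list(out = y, cache = list(mask = attr(y, "mask"), dims = d,
                             l_out = d[3] %/% 2L))
}

maxpool_backward <- function(layer, cache, dy) {
  list(dx = .Call(C_maxpool2_backward, dy, cache$mask,
                  as.integer(cache$dims)))
}

nn_forward <- function(net, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    res <- switch(ly$type,
      dense = {
        y <- .Call(C_add_bias, x %*% ly$W, ly$b)
        list(out = y, cache = list(x = x))
      },
      conv1d = conv1d_forward(ly, x),
      relu = {
        y <- .Call(C_relu, x)
        list(out = y, cache = list(mask = attr(y, "mask")))
      },
      tanh = {
        y <- tanh(x)
        list(out = y, cache = list(y = y))
      },
      maxpool = maxpool_forward(ly, x),
      flatten = {
        d <- dim(x)
        list(out = matrix(x, d[1], prod(d[-1])), cache = list(dims = d))
      }
    )
    x <- res$out
    if (keep_cache) caches[[i]] <- res$cache
  }
  list(out = x, caches = caches)
}

# returns per-layer parameter gradients and the gradient wrt the input;
# param_grads = FALSE skips the dW/db GEMMs (input gradient only)
nn_backward <- function(net, caches, dy, param_grads = TRUE) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "dense") {
      if (param_grads)
        grads[[i]] <- list(dW = crossprod(ca$x, dy), db = colSums(dy))
      dy <- tcrossprod(dy, ly$W)
    } else if (ly$type == "conv1d") {
      g <- conv1d_backward(ly, ca, dy, param_grads)
      grads[[i]] <- if (param_grads) list(dW = g$dW, db = g$db)
      dy <- g$dx
    } else if (ly$type == "relu") {
      dy <- .Call(C_mask_mul, dy, ca$mask)
    } else if (ly$type == "tanh") {
      dy <- dy * (1 - ca$y^2)
    } else if (ly$type == "maxpool") {
      dy <- maxpool_backward(ly, ca, dy)$dx
    } else if (ly$type == "flatten") {
      dy <- array(dy, dim = ca$dims)
    }
  }
  list(grads = grads, dx = dy)
}

nn_n_params <- function(net) {
  sum(vapply(net$layers, function(ly) {
    if (!is.null(ly$W)) length(ly$W) + length(ly$b) else 0L
  }, integer(1)))
}

nn_adam_state <- function(net) {
  lapply(net$layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    list(mW = array(0, dim = dim(ly$W) %||% length(ly$W)),
         vW = array(0, dim = dim(ly$W) %||% length(ly$W)),
         mb = numeric(length(ly$b)), vb = numeric(length(ly$b)), t = 0L)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adam step, fused in C and in place: the caller must own net's parameter
# arrays exclusively (see nn_deep_copy)
nn_adam_step <- function(net, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- state[[i]]
    st$t <- st$t + 1L
    .Call(C_adam_step, net$layers[[i]]$W, st$mW, st$vW, g$dW,
          lr, beta1, beta2, eps, as.numeric(st$t))
    .Call(C_adam_step, net$layers[[i]]$b, st$mb, st$vb, g$db,
          lr, beta1, beta2, eps, as.numeric(st$t))
    state[[i]] <- st
  }
  list(net = net, state = state)
}

# polyak averaging of target network parameters, in place on the target
nn_soft_update <- function(target, source, tau) {
  for (i in seq_along(target$layers)) {
    if (is.null(target$layers[[i]]$W)) next
    .Call(C_soft_update, target$layers[[i]]$W, source$layers[[i]]$W, tau)
    .Call(C_soft_update, target$layers[[i]]$b, source$layers[[i]]$b, tau)
  }
  target
}

# force fresh allocations of all learnable parameters so in-place updates
# cannot leak across logical copies of a network
nn_deep_copy <- function(net) {
  for (i in seq_along(net$layers)) {
    if (is.null(net$layers[[i]]$W)) next
    net$layers[[i]]$W <- net$layers[[i]]$W + 0
    net$layers[[i]]$b <- net$layers[[i]]$b + 0
  }
  net
}

critic_deep_copy <- function(critic) {
  critic$trunk <- nn_deep_copy(critic$trunk)
  critic$head <- nn_deep_copy(critic$head)
  critic
}
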