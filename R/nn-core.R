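# Minimal reverse-mode network engine on base R matrix operations.
#
# A network is a list of layer objects; each layer carries its parameters,
# gradients and a forward cache.  Forward/backward return updated layer
# lists (R copy semantics; cheap at the batch sizes used here).  Temporal
# data is carried as an (N, T, C) array, feature data as an (N, D) matrix.

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_layer <- function(type, params = list(), state = list(), meta = list()) {
  structure(list(type = type, params = params, grads = NULL,
                 state = state, meta = meta, cache = NULL),
            class = "hs_layer")
}

# He-style initialization; draws come from the caller's seeded RNG stream.
nn_init_mat <- function(n_in, n_out, fan_in = n_in) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan_in)), n_in, n_out)
}

nn_dense <- function(n_in, n_out) {
  nn_layer("dense",
           params = list(W = nn_init_mat(n_in, n_out), b = numeric(n_out)),
           meta = list(n_in = n_in, n_out = n_out))
}

nn_relu <- function() nn_layer("relu")

# Batch norm over an (N, D) matrix (one statistic per column).
nn_bn <- function(d, momentum = 0.1, eps = 1e-5) {
  nn_layer("bn",
           params = list(gamma = rep(1, d), beta = numeric(d)),
           state = list(running_mean = numeric(d), running_var = rep(1, d)),
           meta = list(d = d, momentum = momentum, eps = eps))
}

# Causal dilated 1-D convolution on (N, T, C_in) -> (N, T, C_out).
# Weights: (kernel, C_in, C_out); left zero-padding implies causality.
nn_conv1d <- function(c_in, c_out, kernel, dilation = 1) {
  W <- array(stats::rnorm(kernel * c_in * c_out,
                          sd = sqrt(2 / (kernel * c_in))),
             dim = c(kernel, c_in, c_out))
  nn_layer("conv1d",
           params = list(W = W, b = numeric(c_out)),
           meta = list(c_in = c_in, c_out = c_out,
                       kernel = kernel, dilation = dilation))
}

# Batch norm per channel over an (N, T, C) array.
nn_bn_temporal <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- nn_bn(c, momentum, eps)
  l$type <- "bn_temporal"
  l
}

nn_maxpool <- function(size = 2) nn_layer("maxpool", meta = list(size = size))

nn_globalmax <- function() nn_layer("globalmax")

# Residual temporal block: two (conv -> BN -> ReLU) stages plus a skip
# path (identity when channel counts match, pointwise linear otherwise).
# The skip join is additive after the second activation so that zeroing
# the second conv reduces the block to its skip path exactly.
nn_tcn_block <- function(c_in, c_out, kernel, dilation) {
  sub <- list(conv1 = nn_conv1d(c_in, c_out, kernel, dilation),
              bn1   = nn_bn_temporal(c_out),
              relu1 = nn_relu(),
              conv2 = nn_conv1d(c_out, c_out, kernel, dilation),
              bn2   = nn_bn_temporal(c_out),
              relu2 = nn_relu())
  proj <- if (c_in != c_out) nn_conv1d(c_in, c_out, kernel = 1) else NULL
  nn_layer("tcn_block",
           params = list(),
           state = list(sub = sub, proj = proj),
           meta = list(c_in = c_in, c_out = c_out))
}

# Residual fully connected block: dense -> BN -> ReLU twice, additive skip
# (linear projection when widths differ).
nn_resfc_block <- function(n_in, n_out) {
  sub <- list(fc1   = nn_dense(n_in, n_out),
              bn1   = nn_bn(n_out),
              relu1 = nn_relu(),
              fc2   = nn_dense(n_out, n_out),
              bn2   = nn_bn(n_out),
              relu2 = nn_relu())
  proj <- if (n_in != n_out) nn_dense(n_in, n_out) else NULL
  nn_layer("resfc_block",
           state = list(sub = sub, proj = proj),
           meta = list(n_in = n_in, n_out = n_out))
}

## ---- forward ------------------------------------------------------------

shift_right <- function(x, o) {
  # causal shift along the time axis of an (N, T, C) array
  d <- dim(x)
  if (o == 0) return(x)
  xs <- array(0, d)
  if (o < d[2]) xs[, (o + 1):d[2], ] <- x[, 1:(d[2] - o), , drop = FALSE]
  xs
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      out <- sweep(x %*% layer$params$W, 2, layer$params$b, "+")
      layer$cache <- list(x = x)
      list(layer = layer, out = out)
    },
    relu = {
      out <- x
      mask <- x > 0
      out[!mask] <- 0
      layer$cache <- list(mask = mask)
      list(layer = layer, out = out)
    },
    bn = {
      m <- layer$meta
      if (training) {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc^2)
        layer$state$running_mean <- (1 - m$momentum) * layer$state$running_mean +
          m$momentum * mu
        layer$state$running_var <- (1 - m$momentum) * layer$state$running_var +
          m$momentum * v
      } else {
        mu <- layer$state$running_mean
        v <- layer$state$running_var
        xc <- sweep(x, 2, mu)
      }
      inv_std <- 1 / sqrt(v + m$eps)
      xhat <- sweep(xc, 2, inv_std, "*")
      out <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
                   layer$params$beta, "+")
      layer$cache <- list(xhat = xhat, inv_std = inv_std, training = training)
      list(layer = layer, out = out)
    },
    bn_temporal = {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3])
      layer$type <- "bn"
      r <- layer_forward(layer, xm, training)
      r$layer$type <- "bn_temporal"
      r$layer$cache$dim <- d
      list(layer = r$layer, out = array(r$out, d))
    },
    conv1d = {
      m <- layer$meta
      d <- dim(x)
      N <- d[1]; Tt <- d[2]
      outm <- matrix(rep(layer$params$b, each = N * Tt), N * Tt, m$c_out)
      for (k in seq_len(m$kernel)) {
        o <- (k - 1) * m$dilation
        if (o >= Tt) next
        xs <- shift_right(x, o)
        Wk <- matrix(layer$params$W[k, , ], m$c_in, m$c_out)
        outm <- outm + matrix(xs, N * Tt, m$c_in) %*% Wk
      }
      layer$cache <- list(x = x)
      list(layer = layer, out = array(outm, c(N, Tt, m$c_out)))
    },
    maxpool = {
      s <- layer$meta$size
      d <- dim(x)
      Tp <- d[2] %/% s
      if (Tp < 1) stop("maxpool: time axis shorter than pool size")
      out <- array(-Inf, c(d[1], Tp, d[3]))
      arg <- array(1L, c(d[1], Tp, d[3]))
      for (j in seq_len(s)) {
        slice <- x[, (seq_len(Tp) - 1) * s + j, , drop = FALSE]
        upd <- slice > out
        out[upd] <- slice[upd]
        arg[upd] <- j
      }
      layer$cache <- list(arg = arg, dim = d)
      list(layer = layer, out = out)
    },
    globalmax = {
      d <- dim(x)
      out <- apply(x, c(1, 3), max)
      arg <- apply(x, c(1, 3), which.max)
      layer$cache <- list(arg = arg, dim = d)
      list(layer = layer, out = matrix(out, d[1], d[3]))
    },
    tcn_block = ,
    resfc_block = {
      sub <- layer$state$sub
      h <- x
      for (nm in names(sub)) {
        r <- layer_forward(sub[[nm]], h, training)
        sub[[nm]] <- r$layer
        h <- r$out
      }
      skip <- x
      proj <- layer$state$proj
      if (!is.null(proj)) {
        r <- layer_forward(proj, x, training)
        proj <- r$layer
        skip <- r$out
      }
      layer$state$sub <- sub
      layer$state$proj <- proj
      list(layer = layer, out = h + skip)
    },
    stop("unknown layer type: ", layer$type)
  )
}

## ---- backward -----------------------------------------------------------

layer_backward <- function(layer, dout) {
  switch(layer$type,
    dense = {
      x <- layer$cache$x
      layer$grads <- list(W = crossprod(x, dout), b = colSums(dout))
      list(layer = layer, dx = dout %*% t(layer$params$W))
    },
    relu = {
      dx <- dout
      dx[!layer$cache$mask] <- 0
      list(layer = layer, dx = dx)
    },
    bn = {
      c_ <- layer$cache
      m <- nrow(c_$xhat)
      dgamma <- colSums(dout * c_$xhat)
      dbeta <- colSums(dout)
      layer$grads <- list(gamma = dgamma, beta = dbeta)
      g_inv <- layer$params$gamma * c_$inv_std
      if (isTRUE(c_$training)) {
        dx <- sweep(dout * m, 2, dbeta) - sweep(c_$xhat, 2, dgamma, "*")
        dx <- sweep(dx, 2, g_inv / m, "*")
      } else {
        dx <- sweep(dout, 2, g_inv, "*")
      }
      list(layer = layer, dx = dx)
    },
    bn_temporal = {
      d <- layer$cache$dim
      layer$type <- "bn"
      r <- layer_backward(layer, matrix(dout, d[1] * d[2], d[3]))
      r$layer$type <- "bn_temporal"
      list(layer = r$layer, dx = array(r$dx, d))
    },
    conv1d = {
      m <- layer$meta
      x <- layer$cache$x
      d <- dim(x)
      N <- d[1]; Tt <- d[2]
      dm <- matrix(dout, N * Tt, m$c_out)
      dW <- array(0, dim(layer$params$W))
      dxm <- matrix(0, N * Tt, m$c_in)
      dx <- array(0, d)
      for (k in seq_len(m$kernel)) {
        o <- (k - 1) * m$dilation
        if (o >= Tt) next
        xs <- shift_right(x, o)
        dW[k, , ] <- crossprod(matrix(xs, N * Tt, m$c_in), dm)
        Wk <- matrix(layer$params$W[k, , ], m$c_in, m$c_out)
        dxs <- array(dm %*% t(Wk), c(N, Tt, m$c_in))
        # undo the causal shift: contribution lands o steps earlier
        dx[, 1:(Tt - o), ] <- dx[, 1:(Tt - o), , drop = FALSE] +
          dxs[, (o + 1):Tt, , drop = FALSE]
      }
      layer$grads <- list(W = dW, b = colSums(dm))
      list(layer = layer, dx = dx)
    },
    maxpool = {
      s <- layer$meta$size
      d <- layer$cache$dim
      arg <- layer$cache$arg
      Tp <- dim(dout)[2]
      dx <- array(0, d)
      for (j in seq_len(s)) {
        sel <- arg == j
        slice <- array(0, dim(dout))
        slice[sel] <- dout[sel]
        dx[, (seq_len(Tp) - 1) * s + j, ] <- slice
      }
      list(layer = layer, dx = dx)
    },
    globalmax = {
      d <- layer$cache$dim
      arg <- layer$cache$arg
      dx <- array(0, d)
      idx <- cbind(rep(seq_len(d[1]), d[3]),
                   as.vector(arg),
                   rep(seq_len(d[3]), each = d[1]))
      dx[idx] <- as.vector(dout)
      list(layer = layer, dx = dx)
    },
    tcn_block = ,
    resfc_block = {
      sub <- layer$state$sub
      dh <- dout
      for (nm in rev(names(sub))) {
        r <- layer_backward(sub[[nm]], dh)
        sub[[nm]] <- r$layer
        dh <- r$dx
      }
      dskip <- dout
      proj <- layer$state$proj
      if (!is.null(proj)) {
        r <- layer_backward(proj, dout)
        proj <- r$layer
        dskip <- r$dx
      }
      layer$state$sub <- sub
      layer$state$proj <- proj
      list(layer = layer, dx = dh + dskip)
    },
    stop("unknown layer type: ", layer$type)
  )
}

## ---- network helpers ----------------------------------------------------

nn_forward <- function(net, x, training = FALSE) {
  for (i in seq_along(net)) {
    r <- layer_forward(net[[i]], x, training)
    net[[i]] <- r$layer
    x <- r$out
  }
  list(net = net, out = x)
}

nn_backward <- function(net, dout) {
  for (i in rev(seq_along(net))) {
    r <- layer_backward(net[[i]], dout)
    net[[i]] <- r$layer
    dout <- r$dx
  }
  list(net = net, dx = dout)
}

# Flatten parameters (and grads) of a possibly nested layer list into one
# named list, so an optimizer can treat the whole model uniformly.
nn_collect <- function(net, what = c("params", "grads"), prefix = "") {
  what <- match.arg(what)
  out <- list()
  for (i in seq_along(net)) {
    l <- net[[i]]
    tag <- paste0(prefix, "L", i)
    if (l$type %in% c("tcn_block", "resfc_block")) {
      out <- c(out, nn_collect(l$state$sub, what, paste0(tag, ".s.")))
      if (!is.null(l$state$proj))
        out <- c(out, nn_collect(list(l$state$proj), what, paste0(tag, ".p.")))
    } else {
      vals <- if (what == "params") l$params else l$grads
      for (nm in names(vals)) out[[paste0(tag, ".", nm)]] <- vals[[nm]]
    }
  }
  out
}

nn_set_params <- function(net, params, prefix = "") {
  for (i in seq_along(net)) {
    l <- net[[i]]
    tag <- paste0(prefix, "L", i)
    if (l$type %in% c("tcn_block", "resfc_block")) {
      l$state$sub <- nn_set_params(l$state$sub, params, paste0(tag, ".s."))
      if (!is.null(l$state$proj))
        l$state$proj <- nn_set_params(list(l$state$proj), params,
                                      paste0(tag, ".p."))[[1]]
    } else {
      for (nm in names(l$params)) {
        key <- paste0(tag, ".", nm)
        if (!is.null(params[[key]])) {
          p <- params[[key]]
          if (!is.null(dim(l$params[[nm]]))) dim(p) <- dim(l$params[[nm]])
          l$params[[nm]] <- p
        }
      }
    }
    net[[i]] <- l
  }
  net
}

nn_n_params <- function(net) {
  sum(vapply(nn_collect(net, "params"), length, integer(1)))
}

## ---- Adam optimizer -----------------------------------------------------

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L, m = list(), v = list())
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- as.numeric(g)
    m <- opt$m[[nm]] %||% numeric(length(g))
    v <- opt$v[[nm]] %||% numeric(length(g))
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    step <- opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
    p <- params[[nm]]
    d <- dim(p)
    p <- as.numeric(p) - step
    if (!is.null(d)) dim(p) <- d
    params[[nm]] <- p
  }
  list(opt = opt, params = params)
}

# Plain SGD, available as an alternative optimizer.
sgd_step <- function(opt, params, grads) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    p <- params[[nm]]
    d <- dim(p)
    p <- as.numeric(p) - opt$lr * as.numeric(g)
    if (!is.null(d)) dim(p) <- d
    params[[nm]] <- p
  }
  list(opt = opt, params = params)
}
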