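# Minimal CPU layer engine: forward/backward passes for the layer kinds the
# two-stream regressor needs (conv1d, conv2d, batchnorm, relu, avgpool,
# dropout, flatten, dense). Convolutions are computed as shift-and-GEMM so the
# heavy lifting stays in BLAS. Tensors are batch-first arrays: (B, L, C) for
# 1-D streams, (B, H, W, C) for 2-D streams, (B, F) matrices after flatten.

new_layer <- function(kind, spec, params = list()) {
  env <- new.env(parent = emptyenv())
  env$kind <- kind
  env$spec <- spec
  env$params <- params
  env$grads <- list()
  env$cache <- NULL
  env
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# instantiate a layer from its spec given the incoming shape (spatial dims +
# channels, without the batch dimension); returns list(layer, out_shape)
layer_init <- function(spec, in_shape) {
  kind <- spec$kind
  if (kind == "conv1d") {
    K <- spec$kernel; Cin <- in_shape[2]; F <- spec$filters
    layer <- new_layer(kind, spec, list(
      W = he_init(c(K, Cin, F), K * Cin),
      b = numeric(F)
    ))
    list(layer = layer, out_shape = c(in_shape[1], F))
  } else if (kind == "conv2d") {
    Kh <- spec$kernel[1]; Kw <- spec$kernel[2]
    Cin <- in_shape[3]; F <- spec$filters
    layer <- new_layer(kind, spec, list(
      W = he_init(c(Kh, Kw, Cin, F), Kh * Kw * Cin),
      b = numeric(F)
    ))
    list(layer = layer, out_shape = c(in_shape[1], in_shape[2], F))
  } else if (kind == "batchnorm") {
    C <- in_shape[length(in_shape)]
    layer <- new_layer(kind, spec, list(gamma = rep(1, C), beta = numeric(C)))
    layer$run_mean <- numeric(C)
    layer$run_var <- rep(1, C)
    layer$momentum <- 0.9
    list(layer = layer, out_shape = in_shape)
  } else if (kind == "relu") {
    list(layer = new_layer(kind, spec), out_shape = in_shape)
  } else if (kind == "avgpool") {
    ss <- spec$pool
    if (ss < 2) stop("pooling factor must be >= 2")
    spatial <- in_shape[-length(in_shape)] %/% ss
    if (any(spatial < 1)) {
      stop("feature map ", paste(in_shape, collapse = "x"),
           " too small for pooling factor ", ss)
    }
    list(layer = new_layer(kind, spec),
         out_shape = c(spatial, in_shape[length(in_shape)]))
  } else if (kind == "dropout") {
    if (spec$rate < 0 || spec$rate >= 1) stop("dropout rate must be in [0, 1)")
    list(layer = new_layer(kind, spec), out_shape = in_shape)
  } else if (kind == "flatten") {
    list(layer = new_layer(kind, spec), out_shape = prod(in_shape))
  } else if (kind == "dense") {
    Fin <- in_shape[1]; Fout <- spec$units
    layer <- new_layer(kind, spec, list(
      W = he_init(c(Fin, Fout), Fin),
      b = numeric(Fout)
    ))
    list(layer = layer, out_shape = Fout)
  } else {
    stop("unknown layer kind: ", kind)
  }
}

# ---- conv1d -----------------------------------------------------------------

conv1d_forward <- function(layer, x) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  W <- layer$params$W; K <- dim(W)[1]; F <- dim(W)[3]
  pl <- (K - 1L) %/% 2L
  xp <- array(0, c(B, L + K - 1L, Cin))
  xp[, pl + seq_len(L), ] <- x
  y <- matrix(rep(layer$params$b, each = B * L), B * L, F)
  for (k in seq_len(K)) {
    Xs <- xp[, k:(k + L - 1L), , drop = FALSE]
    dim(Xs) <- c(B * L, Cin)
    y <- y + Xs %*% matrix(W[k, , ], Cin, F)
  }
  layer$cache <- list(xp = xp, B = B, L = L, Cin = Cin)
  dim(y) <- c(B, L, F)
  y
}

conv1d_backward <- function(layer, dy) {
  cc <- layer$cache
  B <- cc$B; L <- cc$L; Cin <- cc$Cin
  W <- layer$params$W; K <- dim(W)[1]; F <- dim(W)[3]
  pl <- (K - 1L) %/% 2L
  dym <- dy; dim(dym) <- c(B * L, F)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(cc$xp))
  for (k in seq_len(K)) {
    Xs <- cc$xp[, k:(k + L - 1L), , drop = FALSE]
    dim(Xs) <- c(B * L, Cin)
    dW[k, , ] <- crossprod(Xs, dym)
    dXs <- dym %*% t(matrix(W[k, , ], Cin, F))
    dim(dXs) <- c(B, L, Cin)
    dxp[, k:(k + L - 1L), ] <- dxp[, k:(k + L - 1L), , drop = FALSE] + dXs
  }
  layer$grads <- list(W = dW, b = colSums(dym))
  dxp[, pl + seq_len(L), , drop = FALSE]
}

# ---- conv2d -----------------------------------------------------------------

conv2d_forward <- function(layer, x) {
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Wt <- layer$params$W
  Kh <- dim(Wt)[1]; Kw <- dim(Wt)[2]; F <- dim(Wt)[4]
  ph <- (Kh - 1L) %/% 2L; pw <- (Kw - 1L) %/% 2L
  xp <- array(0, c(B, H + Kh - 1L, Wd + Kw - 1L, Cin))
  xp[, ph + seq_len(H), pw + seq_len(Wd), ] <- x
  y <- matrix(rep(layer$params$b, each = B * H * Wd), B * H * Wd, F)
  for (kh in seq_len(Kh)) {
    for (kw in seq_len(Kw)) {
      Xs <- xp[, kh:(kh + H - 1L), kw:(kw + Wd - 1L), , drop = FALSE]
      dim(Xs) <- c(B * H * Wd, Cin)
      y <- y + Xs %*% matrix(Wt[kh, kw, , ], Cin, F)
    }
  }
  layer$cache <- list(xp = xp, B = B, H = H, W = Wd, Cin = Cin)
  dim(y) <- c(B, H, Wd, F)
  y
}

conv2d_backward <- function(layer, dy) {
  cc <- layer$cache
  B <- cc$B; H <- cc$H; Wd <- cc$W; Cin <- cc$Cin
  Wt <- layer$params$W
  Kh <- dim(Wt)[1]; Kw <- dim(Wt)[2]; F <- dim(Wt)[4]
  ph <- (Kh - 1L) %/% 2L; pw <- (Kw - 1L) %/% 2L
  dym <- dy; dim(dym) <- c(B * H * Wd, F)
  dW <- array(0, dim(Wt))
  dxp <- array(0, dim(cc$xp))
  for (kh in seq_len(Kh)) {
    for (kw in seq_len(Kw)) {
      Xs <- cc$xp[, kh:(kh + H - 1L), kw:(kw + Wd - 1L), , drop = FALSE]
      dim(Xs) <- c(B * H * Wd, Cin)
      dW[kh, kw, , ] <- crossprod(Xs, dym)
      dXs <- dym %*% t(matrix(Wt[kh, kw, , ], Cin, F))
      dim(dXs) <- c(B, H, Wd, Cin)
      dxp[, kh:(kh + H - 1L), kw:(kw + Wd - 1L), ] <-
        dxp[, kh:(kh + H - 1L), kw:(kw + Wd - 1L), , drop = FALSE] + dXs
    }
  }
  layer$grads <- list(W = dW, b = colSums(dym))
  dxp[, ph + seq_len(H), pw + seq_len(Wd), , drop = FALSE]
}

# ---- batchnorm (channels-last, population statistics) -----------------------

batchnorm_forward <- function(layer, x, training) {
  d <- dim(x); C <- d[length(d)]; M <- prod(d) / C
  xm <- x; dim(xm) <- c(M, C)
  eps <- 1e-5
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
  layer$cache <- list(xhat = xhat, invstd = invstd, dims = d, training = training)
  dim(y) <- d
  y
}

batchnorm_backward <- function(layer, dy) {
  cc <- layer$cache
  d <- cc$dims; C <- d[length(d)]; M <- prod(d) / C
  dym <- dy; dim(dym) <- c(M, C)
  layer$grads <- list(gamma = colSums(dym * cc$xhat), beta = colSums(dym))
  dxhat <- sweep(dym, 2, layer$params$gamma, "*")
  if (cc$training) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cc$xhat)
    dx <- sweep(dxhat, 2, m1, "-") - sweep(cc$xhat, 2, m2, "*")
    dx <- sweep(dx, 2, cc$invstd, "*")
  } else {
    dx <- sweep(dxhat, 2, cc$invstd, "*")
  }
  dim(dx) <- d
  dx
}

# ---- avgpool (factor ss along every spatial dim) ----------------------------

avgpool_forward <- function(layer, x) {
  ss <- layer$spec$pool
  d <- dim(x)
  layer$cache <- list(in_dim = d)
  if (length(d) == 3L) {          # (B, L, C)
    L2 <- d[2] %/% ss
    y <- array(0, c(d[1], L2, d[3]))
    for (o in seq_len(ss)) {
      y <- y + x[, seq.int(o, by = ss, length.out = L2), , drop = FALSE]
    }
    y / ss
  } else {                        # (B, H, W, C)
    H2 <- d[2] %/% ss; W2 <- d[3] %/% ss
    y <- array(0, c(d[1], H2, W2, d[4]))
    for (oh in seq_len(ss)) {
      for (ow in seq_len(ss)) {
        y <- y + x[, seq.int(oh, by = ss, length.out = H2),
                   seq.int(ow, by = ss, length.out = W2), , drop = FALSE]
      }
    }
    y / (ss * ss)
  }
}

avgpool_backward <- function(layer, dy) {
  ss <- layer$spec$pool
  d <- layer$cache$in_dim
  dx <- array(0, d)
  if (length(d) == 3L) {
    L2 <- d[2] %/% ss
    g <- dy / ss
    for (o in seq_len(ss)) {
      dx[, seq.int(o, by = ss, length.out = L2), ] <- g
    }
  } else {
    H2 <- d[2] %/% ss; W2 <- d[3] %/% ss
    g <- dy / (ss * ss)
    for (oh in seq_len(ss)) {
      for (ow in seq_len(ss)) {
        dx[, seq.int(oh, by = ss, length.out = H2),
           seq.int(ow, by = ss, length.out = W2), ] <- g
      }
    }
  }
  dx
}

# ---- simple layers ----------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$kind,
    conv1d = conv1d_forward(layer, x),
    conv2d = conv2d_forward(layer, x),
    batchnorm = batchnorm_forward(layer, x, training),
    relu = {
      layer$cache <- x > 0
      x * layer$cache
    },
    avgpool = avgpool_forward(layer, x),
    dropout = {
      if (training && layer$spec$rate > 0) {
        mask <- array((runif(length(x)) >= layer$spec$rate) /
                        (1 - layer$spec$rate), dim(x))
        layer$cache <- mask
        x * mask
      } else {
        layer$cache <- NULL
        x
      }
    },
    flatten = {
      d <- dim(x)
      layer$cache <- d
      dim(x) <- c(d[1], prod(d[-1]))
      x
    },
    dense = {
      layer$cache <- x
      sweep(x %*% layer$params$W, 2, layer$params$b, "+")
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

layer_backward <- function(layer, dy) {
  switch(layer$kind,
    conv1d = conv1d_backward(layer, dy),
    conv2d = conv2d_backward(layer, dy),
    batchnorm = batchnorm_backward(layer, dy),
    relu = dy * layer$cache,
    avgpool = avgpool_backward(layer, dy),
    dropout = if (is.null(layer$cache)) dy else dy * layer$cache,
    flatten = {
      dim(dy) <- layer$cache
      dy
    },
    dense = {
      layer$grads <- list(W = crossprod(layer$cache, dy), b = colSums(dy))
      dy %*% t(layer$params$W)
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

# ---- Adam -------------------------------------------------------------------

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (layer in layers) {
    if (length(layer$params) == 0L) next
    if (is.null(layer$opt)) {
      layer$opt <- lapply(layer$params, function(p) {
        list(m = array(0, dim(p) %||% length(p)),
             v = array(0, dim(p) %||% length(p)))
      })
    }
    for (nm in names(layer$params)) {
      g <- layer$grads[[nm]]
      st <- layer$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      layer$opt[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layer$params[[nm]] <- layer$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
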