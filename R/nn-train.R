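# Model instantiation, the training loop (MSE loss, Adam, early stopping) and
# prediction. Targets are z-scored internally from the training set and mapped
# back to mmHg at prediction time, which keeps the loss surface well scaled for
# the default learning rate.

instantiate_stream <- function(specs, input_shape) {
  layers <- vector("list", length(specs))
  shape <- as.integer(input_shape)
  for (i in seq_along(specs)) {
    init <- layer_init(specs[[i]], shape)
    layers[[i]] <- init$layer
    shape <- as.integer(init$out_shape)
  }
  list(layers = layers, out_shape = shape)
}

stream_forward <- function(layers, x, training) {
  for (layer in layers) x <- layer_forward(layer, x, training)
  x
}

stream_backward <- function(layers, dy) {
  for (layer in rev(layers)) dy <- layer_backward(layer, dy)
  dy
}

fusion_layer_init <- function(fusion, f1, f2) {
  env <- new.env(parent = emptyenv())
  env$kind <- paste0("fuse_", fusion)
  env$spec <- list(fusion = fusion, f1 = f1, f2 = f2)
  env$params <- if (fusion == "conv") {
    list(W = he_init(c(f1 + f2, f1), f1 + f2), b = numeric(f1))
  } else list()
  env$grads <- list()
  env
}

fusion_forward <- function(env, a, b) {
  switch(env$spec$fusion,
    none = if (is.null(a)) b else a,
    concat = cbind(a, b),
    sum = a + b,
    max = {
      env$cache <- a >= b
      pmax(a, b)
    },
    conv = {
      x <- cbind(a, b)
      env$cache <- x
      sweep(x %*% env$params$W, 2, env$params$b, "+")
    })
}

fusion_backward <- function(env, dy) {
  f1 <- env$spec$f1; f2 <- env$spec$f2
  switch(env$spec$fusion,
    none = list(d1 = dy, d2 = dy),
    concat = list(d1 = dy[, seq_len(f1), drop = FALSE],
                  d2 = dy[, f1 + seq_len(f2), drop = FALSE]),
    sum = list(d1 = dy, d2 = dy),
    max = list(d1 = dy * env$cache, d2 = dy * (!env$cache)),
    conv = {
      env$grads <- list(W = crossprod(env$cache, dy), b = colSums(dy))
      dx <- dy %*% t(env$params$W)
      list(d1 = dx[, seq_len(f1), drop = FALSE],
           d2 = dx[, f1 + seq_len(f2), drop = FALSE])
    })
}

# instantiate all weights of a model spec; seeded for reproducibility
nn_build <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "bp_model_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  s1 <- s2 <- NULL
  f1 <- f2 <- 0L
  if (!is.null(spec$stream_1d)) {
    s1 <- instantiate_stream(spec$stream_1d, attr(spec$stream_1d, "input_shape"))
    f1 <- s1$out_shape
  }
  if (!is.null(spec$stream_2d)) {
    s2 <- instantiate_stream(spec$stream_2d, attr(spec$stream_2d, "input_shape"))
    f2 <- s2$out_shape
  }
  fusion <- fusion_layer_init(spec$fusion, f1, f2)
  head_in <- fused_width(spec$fusion, f1, f2)
  head <- instantiate_stream(spec$head, head_in)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(spec = spec, stream_1d = s1, stream_2d = s2,
                 fusion = fusion, head = head,
                 norm = list(mean = 0, sd = 1), history = NULL,
                 trained = FALSE, seed = as.integer(seed)),
            class = "bp_cnn_model")
}

model_layers <- function(model) {
  c(if (!is.null(model$stream_1d)) model$stream_1d$layers,
    if (!is.null(model$stream_2d)) model$stream_2d$layers,
    list(model$fusion),
    model$head$layers)
}

# x1: (B, window) matrix or NULL; x2: (B, side, side) array or NULL
model_forward <- function(model, x1, x2, training = FALSE) {
  f1 <- f2 <- NULL
  if (!is.null(model$stream_1d)) {
    if (is.null(x1)) stop("this model needs the 1-D segment input")
    dim(x1) <- c(dim(x1)[1], dim(x1)[2], 1L)
    f1 <- stream_forward(model$stream_1d$layers, x1, training)
  }
  if (!is.null(model$stream_2d)) {
    if (is.null(x2)) stop("this model needs the FRP input")
    dim(x2) <- c(dim(x2)[1:3], 1L)
    f2 <- stream_forward(model$stream_2d$layers, x2, training)
  }
  h <- fusion_forward(model$fusion, f1, f2)
  stream_forward(model$head$layers, h, training)
}

model_backward <- function(model, dy) {
  dh <- stream_backward(model$head$layers, dy)
  d <- fusion_backward(model$fusion, dh)
  if (!is.null(model$stream_1d)) stream_backward(model$stream_1d$layers, d$d1)
  if (!is.null(model$stream_2d)) {
    stream_backward(model$stream_2d$layers,
                    if (is.null(model$stream_1d)) d$d1 else d$d2)
  }
  invisible(NULL)
}

snapshot_params <- function(model) {
  lapply(model_layers(model), function(l) {
    list(params = l$params,
         run_mean = l$run_mean, run_var = l$run_var)
  })
}

restore_params <- function(model, snap) {
  layers <- model_layers(model)
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$run_mean)) {
      layers[[i]]$run_mean <- snap[[i]]$run_mean
      layers[[i]]$run_var <- snap[[i]]$run_var
    }
  }
  invisible(model)
}

check_dataset <- function(ds, spec, name) {
  if (is.null(ds$y) || length(ds$y) == 0L) stop("empty ", name, " set")
  n <- length(ds$y)
  if (!is.null(spec$stream_1d)) {
    if (is.null(ds$x1)) stop(name, " set lacks 1-D segments (x1)")
    if (nrow(ds$x1) != n || ncol(ds$x1) != spec$window) {
      stop(name, " x1 must be ", n, " x ", spec$window)
    }
  }
  if (!is.null(spec$stream_2d)) {
    if (is.null(ds$x2)) stop(name, " set lacks FRP inputs (x2)")
    d <- dim(ds$x2)
    if (d[1] != n || d[2] != spec$side || d[3] != spec$side) {
      stop(name, " x2 must be ", n, " x ", spec$side, " x ", spec$side)
    }
  }
  invisible(ds)
}

#' Train a blood-pressure regressor
#'
#' Minimises the mean squared error with Adam over minibatches. Validation loss
#' is tracked each epoch; training stops early when it has not improved for
#' `patience` epochs and the best-validation weights are restored. Fully seeded:
#' weight initialisation, shuffling and dropout masks all derive from
#' `hyper$seed`.
#'
#' @param spec a `bp_model_spec` from [build_model_spec()].
#' @param train,val datasets: lists with `x1` (`n x window` matrix of segments),
#'   `x2` (`n x side x side` FRP array) and `y` (targets, mmHg). Streams absent
#'   from the spec may have `NULL` inputs. See [build_dataset()].
#' @param hyper list of hyperparameters: `batch` (100), `lr` (0.001),
#'   `max_epochs` (300), `patience` (30), `seed` (1).
#' @return a trained `bp_cnn_model` whose `history` field holds one row per
#'   epoch (`epoch`, `train_loss`, `val_loss`, in normalised units).
#' @export
train_model <- function(spec, train, val,
                        hyper = list()) {
  hyper <- modifyList(list(batch = 100L, lr = 0.001, max_epochs = 300L,
                           patience = 30L, seed = 1L), hyper)
  check_dataset(train, spec, "training")
  check_dataset(val, spec, "validation")

  model <- nn_build(spec, seed = hyper$seed)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(hyper$seed + 1L)

  mu <- mean(train$y)
  sdy <- max(sd(train$y), 1e-8)
  model$norm <- list(mean = mu, sd = sdy)
  y_tr <- (train$y - mu) / sdy
  y_va <- (val$y - mu) / sdy

  n <- length(y_tr)
  batch <- min(hyper$batch, n)
  layers <- model_layers(model)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf
  best_snap <- NULL
  stall <- 0L
  t_adam <- 0L

  for (epoch in seq_len(hyper$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq.int(1L, n, by = batch)
    tl <- 0
    for (s in starts) {
      bi <- idx[s:min(s + batch - 1L, n)]
      x1b <- if (!is.null(train$x1)) train$x1[bi, , drop = FALSE] else NULL
      x2b <- if (!is.null(train$x2)) train$x2[bi, , , drop = FALSE] else NULL
      pred <- model_forward(model, x1b, x2b, training = TRUE)
      err <- drop(pred) - y_tr[bi]
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (batch starting at ", s, "); lower the learning rate")
      }
      tl <- tl + loss * length(bi)
      model_backward(model, matrix(2 * err / length(bi), ncol = 1))
      t_adam <- t_adam + 1L
      adam_step(layers, hyper$lr, t_adam)
    }
    val_pred <- model_predict_normalised(model, val$x1, val$x2, batch)
    vl <- mean((val_pred - y_va)^2)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl / n,
                                         val_loss = vl))
    if (vl < best_val - 1e-12) {
      best_val <- vl
      best_snap <- snapshot_params(model)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= hyper$patience) break
    }
  }
  if (!is.null(best_snap)) restore_params(model, best_snap)
  model$history <- history
  model$hyper <- hyper
  model$trained <- TRUE
  model
}

# batched eval-mode forward returning normalised predictions
model_predict_normalised <- function(model, x1, x2, batch = 100L) {
  n <- if (!is.null(x1)) nrow(x1) else dim(x2)[1]
  out <- numeric(n)
  for (s in seq.int(1L, n, by = batch)) {
    bi <- s:min(s + batch - 1L, n)
    x1b <- if (!is.null(x1) && !is.null(model$stream_1d)) x1[bi, , drop = FALSE] else NULL
    x2b <- if (!is.null(x2) && !is.null(model$stream_2d)) x2[bi, , , drop = FALSE] else NULL
    out[bi] <- drop(model_forward(model, x1b, x2b, training = FALSE))
  }
  out
}

#' Predict blood pressure from segments and their recurrence plots
#'
#' @param object a trained `bp_cnn_model`.
#' @param x1 `n x window` matrix of raw segments (or a single segment vector);
#'   `NULL` for 2-D-only models.
#' @param x2 `n x side x side` array of fuzzy recurrence plots (or a single
#'   `side x side` matrix); `NULL` for 1-D-only models.
#' @param batch prediction batch size.
#' @param ... unused.
#' @return numeric vector of predictions in mmHg, in input order.
#' @export
predict.bp_cnn_model <- function(object, x1 = NULL, x2 = NULL, batch = 100L, ...) {
  if (!is.null(x1) && is.null(dim(x1))) x1 <- matrix(x1, nrow = 1)
  if (!is.null(x2) && length(dim(x2)) == 2L) {
    x2 <- array(x2, c(1L, dim(x2)))
  }
  if (!is.null(object$stream_1d)) {
    if (is.null(x1)) stop("this model needs the 1-D segment input 'x1'")
    if (ncol(x1) != object$spec$window) {
      stop("x1 has ", ncol(x1), " columns; the model expects ", object$spec$window)
    }
  }
  if (!is.null(object$stream_2d)) {
    if (is.null(x2)) stop("this model needs the FRP input 'x2'")
    if (dim(x2)[2] != object$spec$side || dim(x2)[3] != object$spec$side) {
      stop("x2 side is ", dim(x2)[2], "; the model expects ", object$spec$side)
    }
  }
  z <- model_predict_normalised(object, x1, x2, batch)
  z * object$norm$sd + object$norm$mean
}

#' @export
print.bp_cnn_model <- function(x, ...) {
  cat(sprintf("<bp_cnn_model> %s for %s, %s\n", x$spec$type, toupper(x$spec$target),
              if (x$trained) sprintf("trained %d epochs (best val loss %.4g)",
                                     nrow(x$history), min(x$history$val_loss))
              else "untrained"))
  invisible(x)
}

#' Save / load a trained model
#'
#' The model is serialised as a plain list of weights, batch-norm running
#' statistics, the architecture spec and the target normalisation, so a
#' reloaded model reproduces predictions exactly.
#'
#' @param model a `bp_cnn_model`.
#' @param path file path (RDS).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   rebuilt `bp_cnn_model`.
#' @export
save_model <- function(model, path) {
  state <- list(spec = model$spec, seed = model$seed, norm = model$norm,
                hyper = model$hyper, history = model$history,
                trained = model$trained, layers = snapshot_params(model))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  model <- nn_build(state$spec, seed = state$seed %||% 1L)
  restore_params(model, state$layers)
  model$norm <- state$norm
  model$hyper <- state$hyper
  model$history <- state$history
  model$trained <- state$trained
  model
}

#' Assemble a training dataset from segments
#'
#' Computes the fuzzy recurrence plot of every segment (when the model uses the
#' 2-D stream) and stacks segments, plots and targets into the arrays
#' [train_model()] consumes.
#'
#' @param segments list of [ppg_segment()]s, all of one length.
#' @param target `"sbp"` or `"dbp"`.
#' @param side FRP side; `NULL` skips FRP computation (1-D-only models).
#' @param m,tau,c,omega,alpha,max_iter,seed passed to [segment_to_frp()].
#' @return list with `x1` (`n x window` matrix), `x2` (`n x side x side` array
#'   or `NULL`) and `y` (numeric targets in mmHg).
#' @export
build_dataset <- function(segments, target = c("sbp", "dbp"), side = 88L,
                          m = 3L, tau = 5L, c = 3L, omega = 2, alpha = 1e-5,
                          max_iter = 300L, seed = 1L) {
  target <- match.arg(target)
  if (length(segments) == 0L) stop("no segments supplied")
  window <- length(segments[[1]]$samples)
  x1 <- t(vapply(segments, function(s) {
    if (length(s$samples) != window) stop("segments differ in length")
    s$samples
  }, numeric(window)))
  y <- vapply(segments, function(s) s[[target]], numeric(1))
  x2 <- NULL
  if (!is.null(side)) {
    x2 <- array(0, c(length(segments), side, side))
    for (i in seq_along(segments)) {
      x2[i, , ] <- segment_to_frp(segments[[i]], side = side, m = m, tau = tau,
                                  c = c, omega = omega, alpha = alpha,
                                  max_iter = max_iter, seed = seed)$M
    }
  }
  list(x1 = x1, x2 = x2, y = y)
}
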