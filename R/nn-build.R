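# Layer specifications and the default two-stream architecture: a 1-D
# convolutional stream over the raw segment, a 2-D stream over its fuzzy
# recurrence plot, fused (by concatenation by default) ahead of a dense head.

layer_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' Fuse two feature maps
#'
#' The four fusion operators for co-located feature maps `a` and `b` of shape
#' `H x W x N` (plain vectors are treated as `1 x 1 x N` maps):
#'
#' * `"sum"` — elementwise `a + b` (identical shapes required);
#' * `"max"` — elementwise maximum (identical shapes required);
#' * `"concat"` — channel stacking, output has `2N` channels (equal `H`, `W`);
#' * `"conv"` — channel stacking followed by a 1x1 convolution with a filter
#'   bank `f` of shape `1 x 1 x 2N x N_out` and bias `bias`, restoring `N_out`
#'   channels.
#'
#' @param a,b numeric arrays `H x W x N` (or vectors, promoted to `1 x 1 x N`).
#' @param method one of `"sum"`, `"max"`, `"concat"`, `"conv"`.
#' @param f filter bank for `method = "conv"`, array `1 x 1 x (Na+Nb) x N_out`
#'   (a `(Na+Nb) x N_out` matrix is also accepted).
#' @param bias bias vector of length `N_out` for `method = "conv"` (default 0).
#' @return the fused feature map, an array `H x W x N_out`.
#' @examples
#' fuse(c(1, 2), c(3, 4), "sum")[1, 1, ]
#' fuse(c(1, 2), c(3, 4), "concat")[1, 1, ]
#' @export
fuse <- function(a, b, method = c("concat", "sum", "max", "conv"),
                 f = NULL, bias = NULL) {
  method <- match.arg(method)
  as_map <- function(x) {
    if (is.null(dim(x))) array(x, c(1, 1, length(x))) else {
      if (length(dim(x)) != 3L) stop("feature maps must be H x W x N arrays")
      x
    }
  }
  a <- as_map(a); b <- as_map(b)
  da <- dim(a); db <- dim(b)
  shape_err <- function() {
    stop("fusion '", method, "' cannot combine shapes ",
         paste(da, collapse = "x"), " and ", paste(db, collapse = "x"))
  }
  if (method %in% c("sum", "max")) {
    if (!all(da == db)) shape_err()
    return(if (method == "sum") a + b else pmax(a, b))
  }
  if (!all(da[1:2] == db[1:2])) shape_err()
  y <- array(c(a, b), c(da[1], da[2], da[3] + db[3]))
  if (method == "concat") return(y)
  # conv fusion: 1x1 convolution over the stacked channels
  n2 <- da[3] + db[3]
  if (is.null(f)) stop("conv fusion requires a filter bank 'f'")
  fm <- if (length(dim(f)) == 4L) {
    if (dim(f)[1] != 1L || dim(f)[2] != 1L || dim(f)[3] != n2) {
      stop("conv-fusion filter bank must be 1 x 1 x ", n2, " x N_out")
    }
    matrix(f, n2, dim(f)[4])
  } else {
    f <- as.matrix(f)
    if (nrow(f) != n2) stop("conv-fusion filter bank must have ", n2, " rows")
    f
  }
  n_out <- ncol(fm)
  if (is.null(bias)) bias <- numeric(n_out)
  ym <- matrix(y, da[1] * da[2], n2) %*% fm
  ym <- sweep(ym, 2, bias, "+")
  array(ym, c(da[1], da[2], n_out))
}

#' Build the 1-D convolutional stream
#'
#' Six convolutional blocks over the raw segment, every kernel of length 25:
#' filters 32, 32, 64, 64, 128, 128 by default, each conv followed by batch
#' normalisation and ReLU; average pooling (factor 2) after blocks 1-4;
#' dropout (0.25) after blocks 5 and 6; flatten at the end.
#'
#' @param cfg list of overrides: `window` (input length, default 1024),
#'   `filters`, `kernel` (default 25), `pool_after` (block indices, default
#'   1:4), `dropout_after` (default 5:6), `dropout_rate` (default 0.25).
#' @return ordered list of layer specs (class `stream_spec`), with the input
#'   shape attached as attribute `input_shape`.
#' @export
build_1d_stream <- function(cfg = list()) {
  cfg <- modifyList(list(window = 1024L, filters = c(32L, 32L, 64L, 64L, 128L, 128L),
                         kernel = 25L, pool_after = 1:4, dropout_after = 5:6,
                         dropout_rate = 0.25), cfg)
  if (any(cfg$filters < 1L)) stop("all filter counts must be positive")
  if (cfg$kernel < 1L) stop("kernel length must be positive")
  n_pool <- length(cfg$pool_after)
  if (cfg$window %/% 2L^n_pool < 1L) {
    stop("window ", cfg$window, " collapses under ", n_pool,
         " pooling layers; use a longer window")
  }
  specs <- list()
  for (i in seq_along(cfg$filters)) {
    specs <- c(specs, list(
      layer_spec("conv1d", kernel = cfg$kernel, filters = cfg$filters[i]),
      layer_spec("batchnorm"),
      layer_spec("relu")
    ))
    if (i %in% cfg$pool_after) specs <- c(specs, list(layer_spec("avgpool", pool = 2L)))
    if (i %in% cfg$dropout_after) {
      specs <- c(specs, list(layer_spec("dropout", rate = cfg$dropout_rate)))
    }
  }
  specs <- c(specs, list(layer_spec("flatten")))
  structure(specs, class = "stream_spec", input_shape = c(cfg$window, 1L))
}

#' Build the 2-D convolutional stream
#'
#' Exactly seven 3x3 convolutional layers over the fuzzy recurrence plot
#' (default filters 16, 32, 32, 64, 64, 128, 128), each followed by batch
#' normalisation and ReLU; a 2x2 average pooling after every ReLU except the
#' last two; flatten at the end. Sides below 32 do not survive the five
#' poolings and are rejected.
#'
#' @param cfg list of overrides: `side` (input side, default 88), `filters`,
#'   `kernel` (default `c(3, 3)`), `pool_after` (default 1:5).
#' @return ordered list of layer specs (class `stream_spec`) with attribute
#'   `input_shape`.
#' @export
build_2d_stream <- function(cfg = list()) {
  cfg <- modifyList(list(side = 88L,
                         filters = c(16L, 32L, 32L, 64L, 64L, 128L, 128L),
                         kernel = c(3L, 3L), pool_after = 1:5), cfg)
  if (any(cfg$filters < 1L)) stop("all filter counts must be positive")
  if (cfg$side < 32L) {
    stop("FRP side ", cfg$side, " is too small to survive ",
         length(cfg$pool_after), " poolings; use side >= 32")
  }
  specs <- list()
  for (i in seq_along(cfg$filters)) {
    specs <- c(specs, list(
      layer_spec("conv2d", kernel = cfg$kernel, filters = cfg$filters[i]),
      layer_spec("batchnorm"),
      layer_spec("relu")
    ))
    if (i %in% cfg$pool_after) specs <- c(specs, list(layer_spec("avgpool", pool = 2L)))
  }
  specs <- c(specs, list(layer_spec("flatten")))
  structure(specs, class = "stream_spec",
            input_shape = c(cfg$side, cfg$side, 1L))
}

#' Propagate shapes through a stream
#'
#' Computes the output shape of a stream spec from its input shape without
#' instantiating any weights: same-padded convolutions keep spatial dims and
#' set the channel count, pooling floor-divides spatial dims, flatten collapses
#' everything.
#'
#' @param specs a `stream_spec` or plain list of layer specs.
#' @param input_shape integer vector (spatial dims, then channels); defaults to
#'   the spec's `input_shape` attribute.
#' @return integer vector, the shape after the last layer (a single length for
#'   flattened outputs).
#' @export
stream_output_shape <- function(specs, input_shape = attr(specs, "input_shape")) {
  shape <- as.integer(input_shape)
  for (sp in specs) {
    shape <- switch(sp$kind,
      conv1d = c(shape[1], sp$filters),
      conv2d = c(shape[1], shape[2], sp$filters),
      avgpool = {
        s <- c(shape[-length(shape)] %/% sp$pool, shape[length(shape)])
        if (any(s < 1L)) stop("shape collapses at a pooling layer")
        s
      },
      flatten = prod(shape),
      dense = sp$units,
      shape  # batchnorm / relu / dropout keep the shape
    )
  }
  as.integer(shape)
}

default_head <- function(dropout_rate = 0.25) {
  list(
    layer_spec("dense", units = 256L),
    layer_spec("relu"),
    layer_spec("dropout", rate = dropout_rate),
    layer_spec("dense", units = 64L),
    layer_spec("relu"),
    layer_spec("dense", units = 1L)
  )
}

#' Build a model specification
#'
#' Assembles a regressor spec for one blood-pressure target: a single 1-D
#' stream (`type = "cnn1d"`), a single 2-D stream (`"cnn2d"`), or the
#' two-stream model (`"concat"`) whose flattened stream outputs are fused
#' (concatenation by default, per the headline architecture) ahead of a dense
#' head `256 -> relu -> dropout 0.25 -> 64 -> relu -> 1`. Both streams are
#' trained jointly as a single network. One model estimates one target; SBP and
#' DBP use separate models.
#'
#' @param type `"concat"`, `"cnn1d"` or `"cnn2d"`.
#' @param cfg list of overrides: `window`, `side`, `fusion` (one of `"concat"`,
#'   `"sum"`, `"max"`, `"conv"`), `stream_1d` / `stream_2d` (passed to the
#'   stream builders), `dropout_rate`, `target` (`"sbp"` or `"dbp"`).
#' @return a `bp_model_spec`.
#' @export
build_model_spec <- function(type = c("concat", "cnn1d", "cnn2d"), cfg = list()) {
  type <- match.arg(type)
  cfg <- modifyList(list(window = 1024L, side = 88L, fusion = "concat",
                         stream_1d = list(), stream_2d = list(),
                         dropout_rate = 0.25, target = "sbp"), cfg)
  if (!cfg$target %in% c("sbp", "dbp")) stop("'target' must be \"sbp\" or \"dbp\"")
  s1 <- s2 <- NULL
  if (type %in% c("cnn1d", "concat")) {
    s1 <- build_1d_stream(modifyList(list(window = cfg$window), cfg$stream_1d))
  }
  if (type %in% c("cnn2d", "concat")) {
    s2 <- build_2d_stream(modifyList(list(side = cfg$side), cfg$stream_2d))
  }
  fusion <- if (type == "concat") cfg$fusion else "none"
  if (!fusion %in% c("none", "concat", "sum", "max", "conv")) {
    stop("unknown fusion method: ", fusion)
  }
  if (fusion %in% c("sum", "max", "conv")) {
    f1 <- stream_output_shape(s1)
    f2 <- stream_output_shape(s2)
    if (f1 != f2) {
      stop("fusion '", fusion, "' needs matching stream widths, got ",
           f1, " and ", f2)
    }
  }
  structure(list(type = type, stream_1d = s1, stream_2d = s2, fusion = fusion,
                 head = default_head(cfg$dropout_rate), window = cfg$window,
                 side = cfg$side, target = cfg$target),
            class = "bp_model_spec")
}

#' Build the two-stream concatenation model
#'
#' Convenience wrapper for `build_model_spec("concat", cfg)` — the headline
#' architecture: parallel 1-D and 2-D convolutional streams whose flattened
#' feature maps are joined by concatenation fusion and regressed by a dense
#' head ending in a single linear unit.
#'
#' @inheritParams build_model_spec
#' @return a `bp_model_spec`.
#' @export
build_concat_model <- function(cfg = list()) build_model_spec("concat", cfg)

#' @export
print.bp_model_spec <- function(x, ...) {
  n1 <- if (is.null(x$stream_1d)) 0 else sum(vapply(x$stream_1d, function(s) s$kind == "conv1d", logical(1)))
  n2 <- if (is.null(x$stream_2d)) 0 else sum(vapply(x$stream_2d, function(s) s$kind == "conv2d", logical(1)))
  cat(sprintf("<bp_model_spec> type %s, target %s, fusion %s\n", x$type, x$target, x$fusion))
  cat(sprintf("  1-D stream: %d conv layers (window %d) | 2-D stream: %d conv layers (side %d)\n",
              n1, x$window, n2, x$side))
  invisible(x)
}

#' Count trainable parameters of a model spec
#'
#' @param spec a `bp_model_spec`.
#' @return named vector with per-part and total parameter counts.
#' @export
count_parameters <- function(spec) {
  count_stream <- function(specs, in_shape) {
    if (is.null(specs)) return(0)
    shape <- as.integer(in_shape)
    total <- 0
    for (sp in specs) {
      total <- total + switch(sp$kind,
        conv1d = sp$kernel * shape[2] * sp$filters + sp$filters,
        conv2d = prod(sp$kernel) * shape[3] * sp$filters + sp$filters,
        batchnorm = 2 * shape[length(shape)],
        dense = shape[1] * sp$units + sp$units,
        0)
      shape <- stream_output_shape(list(sp), shape)
    }
    total
  }
  p1 <- count_stream(spec$stream_1d, attr(spec$stream_1d, "input_shape"))
  p2 <- count_stream(spec$stream_2d, attr(spec$stream_2d, "input_shape"))
  f1 <- if (is.null(spec$stream_1d)) 0L else stream_output_shape(spec$stream_1d)
  f2 <- if (is.null(spec$stream_2d)) 0L else stream_output_shape(spec$stream_2d)
  head_in <- fused_width(spec$fusion, f1, f2)
  pf <- if (spec$fusion == "conv") (f1 + f2) * f1 + f1 else 0
  ph <- count_stream(spec$head, head_in)
  c(stream_1d = p1, stream_2d = p2, fusion = pf, head = ph,
    total = p1 + p2 + pf + ph)
}

fused_width <- function(fusion, f1, f2) {
  switch(fusion,
    none = max(f1, f2),
    concat = f1 + f2,
    sum = f1,
    max = f1,
    conv = f1)
}
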