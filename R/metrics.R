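#' Regression metric suite for blood-pressure estimation
#'
#' Computes, over paired target/prediction vectors in mmHg, the six standard
#' quantities reported for cuffless blood-pressure estimators. With errors
#' `e_i = y_i - yhat_i`:
#'
#' * `mae` — mean absolute error, `mean(|e|)`;
#' * `mse` — mean squared error, `mean(e^2)` (mmHg^2);
#' * `me` — mean error (bias), `mean(e)`;
#' * `r2` — coefficient of determination, `1 - sum(e^2) / sum((y - mean(y))^2)`;
#' * `r` — Pearson correlation of `y` and `yhat`;
#' * `std` — population standard deviation of the errors, `sqrt(mean((e - mean(e))^2))`.
#'
#' `std` is the spread of the estimation errors (the quantity the AAMI criterion
#' and the usual "MAE +/- STD" reporting need), with divisor `n`; this gives the
#' exact identity `mse = std^2 + me^2`. When `y` is constant, `r2` and `r` are
#' undefined; when `yhat` is constant, `r` is undefined. Undefined values are
#' returned as `NA` with explicit flags, never silently as 0.
#'
#' @param y numeric vector of reference targets (mmHg).
#' @param yhat numeric vector of predictions (mmHg), same length.
#' @return a `metrics_report`: list with `mae`, `mse`, `me`, `r2`, `r`, `std`,
#'   `n`, and logical flags `r_defined`, `r2_defined`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
compute_metrics <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  n <- length(y)
  if (length(yhat) != n) {
    stop("'y' and 'yhat' must have equal length (", n, " vs ", length(yhat), ")")
  }
  if (n < 2L) stop("at least 2 paired values are required")
  if (!all(is.finite(y)) || !all(is.finite(yhat))) {
    stop("'y' and 'yhat' must be finite")
  }
  e <- y - yhat
  me <- mean(e)
  ss_tot <- sum((y - mean(y))^2)
  y_const <- ss_tot == 0
  yhat_const <- sum((yhat - mean(yhat))^2) == 0
  r2 <- if (y_const) NA_real_ else 1 - sum(e^2) / ss_tot
  r <- if (y_const || yhat_const) NA_real_ else cor(y, yhat)
  structure(list(
    mae = mean(abs(e)),
    mse = mean(e^2),
    me = me,
    r2 = r2,
    r = r,
    std = sqrt(mean((e - me)^2)),
    n = n,
    r_defined = !(y_const || yhat_const),
    r2_defined = !y_const
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  MAE %.3f mmHg | MSE %.3f mmHg^2 | ME %+.3f mmHg | STD %.3f mmHg\n",
              x$mae, x$mse, x$me, x$std))
  cat(sprintf("  R^2 %s | R %s\n",
              if (x$r2_defined) sprintf("%.4f", x$r2) else "undefined (constant target)",
              if (x$r_defined) sprintf("%.4f", x$r) else "undefined (constant series)"))
  invisible(x)
}
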