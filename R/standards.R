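# Device-validation standards for blood-pressure estimators: BHS cumulative
# error grading, the AAMI acceptance rule, and Bland-Altman agreement analysis.

# BHS grade thresholds: cumulative % of |error| within 5 / 10 / 15 mmHg
.bhs_table <- list(
  A = c(60, 85, 95),
  B = c(50, 75, 90),
  C = c(40, 65, 85)
)

#' Cumulative error percentages for BHS grading
#'
#' Percentage of absolute errors within 5, 10 and 15 mmHg. The band boundary is
#' inclusive (`<=`); boundary samples are measure-zero for continuous errors,
#' so this convention affects no realistic grading.
#'
#' @param errors numeric vector of estimation errors in mmHg (sign ignored).
#' @return named numeric vector `c(cum5, cum10, cum15)` in percent.
#' @export
bhs_cumulative <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("'errors' must be nonempty")
  a <- abs(errors)
  c(cum5 = 100 * mean(a <= 5),
    cum10 = 100 * mean(a <= 10),
    cum15 = 100 * mean(a <= 15))
}

#' BHS grade from cumulative percentages
#'
#' A device earns a grade when it meets all three of that grade's thresholds
#' simultaneously: grade A needs at least 60% of absolute errors within 5 mmHg,
#' 85% within 10 mmHg and 95% within 15 mmHg; B needs 50/75/90; C needs
#' 40/65/85. Anything weaker is grade D.
#'
#' @param cum5,cum10,cum15 cumulative percentages (0-100). `cum5` may also be a
#'   length-3 vector as returned by [bhs_cumulative()].
#' @return a single character, `"A"`, `"B"`, `"C"` or `"D"`.
#' @examples
#' bhs_grade(93.42, 97.96, 99.7)
#' @export
bhs_grade <- function(cum5, cum10, cum15) {
  if (length(cum5) == 3L && missing(cum10)) {
    cum15 <- cum5[[3L]]; cum10 <- cum5[[2L]]; cum5 <- cum5[[1L]]
  }
  cums <- c(cum5, cum10, cum15)
  if (any(!is.finite(cums)) || any(cums < 0) || any(cums > 100)) {
    stop("cumulative percentages must lie in [0, 100]")
  }
  for (g in names(.bhs_table)) {
    if (all(cums >= .bhs_table[[g]])) return(g)
  }
  "D"
}

#' AAMI acceptance check
#'
#' The AAMI standard accepts a blood-pressure estimator when the mean error is
#' within +/- 5 mmHg, the standard deviation of the errors is at most 8 mmHg,
#' and more than 85 subjects were assessed.
#'
#' @param me mean error in mmHg.
#' @param std standard deviation of the errors in mmHg.
#' @param subjects number of subjects.
#' @return an `aami_result`: list with `me`, `std`, `subjects`, logical `pass`,
#'   and a character vector `reasons` naming each failed criterion (empty on
#'   pass).
#' @examples
#' aami_check(-0.15, 5.26, 200)
#' @export
aami_check <- function(me, std, subjects) {
  if (subjects < 1) stop("'subjects' must be at least 1")
  reasons <- character(0)
  if (abs(me) > 5) {
    reasons <- c(reasons, sprintf("mean error %.2f mmHg outside +/-5 mmHg", me))
  }
  if (std > 8) {
    reasons <- c(reasons, sprintf("error STD %.2f mmHg exceeds 8 mmHg", std))
  }
  if (subjects <= 85) {
    reasons <- c(reasons, sprintf("%d subjects, more than 85 required", subjects))
  }
  structure(list(me = me, std = std, subjects = as.integer(subjects),
                 pass = length(reasons) == 0L, reasons = reasons),
            class = "aami_result")
}

#' @export
print.aami_result <- function(x, ...) {
  cat(sprintf("<aami_result> ME %+.2f mmHg, STD %.2f mmHg, %d subjects: %s\n",
              x$me, x$std, x$subjects, if (x$pass) "PASS" else "FAIL"))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as estimate minus reference (`yhat - y`). The bias is
#' their mean and the limits of agreement are `bias +/- 1.96 * SD` of the
#' differences (population SD, divisor `n`); `within_fraction` is the fraction
#' of differences falling inside the limits.
#'
#' @param y reference values (mmHg).
#' @param yhat estimates (mmHg), same length, `n >= 2`.
#' @return a `bland_altman` object: list with `bias`, `loa_low`, `loa_high`
#'   (mmHg), `within_fraction`, and `n`.
#' @examples
#' bland_altman(c(120, 122), c(119, 123))
#' @export
bland_altman <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  n <- length(y)
  if (length(yhat) != n) stop("'y' and 'yhat' must have equal length")
  if (n < 2L) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- yhat - y
  bias <- mean(d)
  s <- sqrt(mean((d - bias)^2))
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  structure(list(bias = bias, loa_low = lo, loa_high = hi,
                 within_fraction = mean(d >= lo & d <= hi), n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %+.3f mmHg, LoA [%.3f, %.3f], %.1f%% of %d points within\n",
              x$bias, x$loa_low, x$loa_high, 100 * x$within_fraction, x$n))
  invisible(x)
}
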