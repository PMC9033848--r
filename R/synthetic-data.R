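# Synthetic pulse-waveform generator. Emits pseudo-periodic PPG-like records
# whose per-beat morphology varies monotonically with latent systolic and
# diastolic pressure, so every pipeline stage is testable without clinical data.

#' Generator configuration for synthetic pulse records
#'
#' Each beat is a two-Gaussian template: a systolic wave whose amplitude grows
#' linearly with SBP (`A1 = a0 + a1 * (SBP - 120) / 40`) and a dicrotic wave
#' whose amplitude grows with DBP (`A2 = b0 + b1 * (DBP - 80) / 30`). The beat
#' period is `60 / HR` seconds with per-beat heart-rate jitter; SBP and DBP
#' follow bounded random walks sampled once per beat; additive Gaussian noise
#' and a sinusoidal baseline wander are superimposed. The coupling coefficients
#' only need to make blood pressure recoverable in principle; they do not model
#' any particular cardiovascular system.
#'
#' @param fs sampling rate, Hz.
#' @param duration record length, seconds.
#' @param hr_mean,hr_sd per-beat heart-rate distribution, bpm.
#' @param sbp_start,sbp_step_sd,sbp_bounds systolic random walk: start value,
#'   per-beat step SD, and clamping bounds (mmHg).
#' @param dbp_start,dbp_step_sd,dbp_bounds diastolic random walk, likewise.
#' @param noise_sd additive white-noise SD, amplitude units.
#' @param wander_amp,wander_freq baseline-wander amplitude (amplitude units)
#'   and frequency (Hz).
#' @param a0,a1,b0,b1 BP-to-morphology coupling coefficients.
#' @param seed integer RNG seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(fs = 125, duration = 60,
                             hr_mean = 75, hr_sd = 3,
                             sbp_start = 120, sbp_step_sd = 2,
                             sbp_bounds = c(95, 180),
                             dbp_start = 80, dbp_step_sd = 1.5,
                             dbp_bounds = c(50, 90),
                             noise_sd = 0.02,
                             wander_amp = 0.1, wander_freq = 0.2,
                             a0 = 1.0, a1 = 0.5, b0 = 0.4, b1 = 0.3,
                             seed = 1L) {
  cfg <- list(fs = fs, duration = duration, hr_mean = hr_mean, hr_sd = hr_sd,
              sbp_start = sbp_start, sbp_step_sd = sbp_step_sd,
              sbp_bounds = sbp_bounds, dbp_start = dbp_start,
              dbp_step_sd = dbp_step_sd, dbp_bounds = dbp_bounds,
              noise_sd = noise_sd, wander_amp = wander_amp,
              wander_freq = wander_freq, a0 = a0, a1 = a1, b0 = b0, b1 = b1,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$fs <= 0) stop("'fs' must be positive")
  if (cfg$duration <= 0) stop("'duration' must be positive")
  if (cfg$hr_mean <= 0) stop("'hr_mean' must be positive")
  if (any(c(cfg$hr_sd, cfg$sbp_step_sd, cfg$dbp_step_sd, cfg$noise_sd) < 0)) {
    stop("standard deviations must be >= 0")
  }
  if (length(cfg$sbp_bounds) != 2L || diff(cfg$sbp_bounds) <= 0 ||
      length(cfg$dbp_bounds) != 2L || diff(cfg$dbp_bounds) <= 0) {
    stop("bounds must be increasing (low, high) pairs")
  }
  if (cfg$sbp_bounds[1] <= cfg$dbp_bounds[2]) {
    stop("systolic bounds must lie strictly above diastolic bounds")
  }
  if (!(cfg$sbp_bounds[1] <= cfg$sbp_start && cfg$sbp_start <= cfg$sbp_bounds[2]) ||
      !(cfg$dbp_bounds[1] <= cfg$dbp_start && cfg$dbp_start <= cfg$dbp_bounds[2])) {
    stop("random-walk start values must lie inside their bounds")
  }
  invisible(cfg)
}

clamp <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' Generate one synthetic pulse record
#'
#' Builds a beat train per [generator_config()], with per-sample SBP/DBP label
#' series aligned to the waveform (each sample carries the pressure of the beat
#' it belongs to). Bitwise reproducible for a fixed seed.
#'
#' @param cfg a [generator_config()].
#' @return a `signal_record`: list with `ppg`, `fs`, per-sample `sbp` and `dbp`
#'   label vectors, beat `onsets` (sample indices) and the `config` used.
#' @examples
#' rec <- generate_record(generator_config(duration = 10, seed = 42))
#' length(rec$ppg)
#' @export
generate_record <- function(cfg = generator_config()) {
  validate_generator_config(cfg)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed)

  n <- round(cfg$fs * cfg$duration)
  ppg <- numeric(n)
  sbp_lab <- numeric(n)
  dbp_lab <- numeric(n)
  onsets <- integer(0)

  sbp <- cfg$sbp_start
  dbp <- cfg$dbp_start
  onset <- 1L
  while (onset <= n) {
    hr <- max(30, cfg$hr_mean + if (cfg$hr_sd > 0) rnorm(1, 0, cfg$hr_sd) else 0)
    period <- max(10L, as.integer(round(cfg$fs * 60 / hr)))
    a1 <- cfg$a0 + cfg$a1 * (sbp - 120) / 40
    a2 <- cfg$b0 + cfg$b1 * (dbp - 80) / 30
    phase <- (seq_len(period) - 1) / period
    beat <- a1 * exp(-(phase - 0.30)^2 / (2 * 0.08^2)) +
      a2 * exp(-(phase - 0.65)^2 / (2 * 0.12^2))
    idx <- onset:min(n, onset + period - 1L)
    ppg[idx] <- ppg[idx] + beat[seq_along(idx)]
    sbp_lab[idx] <- sbp
    dbp_lab[idx] <- dbp
    onsets <- c(onsets, onset)
    # walk the pressures once per beat, clamped to their bounds
    if (cfg$sbp_step_sd > 0) sbp <- clamp(sbp + rnorm(1, 0, cfg$sbp_step_sd), cfg$sbp_bounds)
    if (cfg$dbp_step_sd > 0) dbp <- clamp(dbp + rnorm(1, 0, cfg$dbp_step_sd), cfg$dbp_bounds)
    onset <- onset + period
  }

  if (cfg$noise_sd > 0) ppg <- ppg + rnorm(n, 0, cfg$noise_sd)
  if (cfg$wander_amp > 0) {
    t <- (seq_len(n) - 1) / cfg$fs
    ppg <- ppg + cfg$wander_amp * sin(2 * pi * cfg$wander_freq * t)
  }

  structure(list(ppg = ppg, fs = cfg$fs, sbp = sbp_lab, dbp = dbp_lab,
                 onsets = onsets, config = cfg),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d samples @ %g Hz (%.1f s), %s beats\n",
              length(x$ppg), x$fs, length(x$ppg) / x$fs,
              if (is.null(x$onsets)) "unknown" else length(x$onsets)))
  invisible(x)
}

#' Cut a record into fixed-length windows
#'
#' Produces `floor((L - window) / stride) + 1` segments; each segment's SBP/DBP
#' label is the mean of the per-sample labels inside its window.
#'
#' @param record a `signal_record`.
#' @param window window length in samples (default 1024, ~8.2 s at 125 Hz).
#' @param stride hop between window starts in samples; defaults to `window`
#'   (non-overlapping).
#' @return a list of [ppg_segment()]s.
#' @export
segment_record <- function(record, window = 1024L, stride = window) {
  window <- as.integer(window); stride <- as.integer(stride)
  L <- length(record$ppg)
  if (window < 2L || stride < 1L) stop("'window' must be >= 2 and 'stride' >= 1")
  if (L < window) {
    stop("record of ", L, " samples is shorter than the window (", window, ")")
  }
  starts <- seq.int(1L, L - window + 1L, by = stride)
  lapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    ppg_segment(record$ppg[idx], fs = record$fs,
                sbp = mean(record$sbp[idx]), dbp = mean(record$dbp[idx]))
  })
}

#' Chronological train/validation/test split
#'
#' Splits each record's segments chronologically: the first 70% (by default)
#' for training, the next 10% for validation, the remainder for testing, with
#' floor-based counts and the remainder assigned to the test set. Segments from
#' one record never cross splits out of temporal order, and no segment appears
#' in two splits.
#'
#' @param segments either a list of [ppg_segment()]s (one record) or a list of
#'   such lists (one element per record).
#' @param fractions length-3 numeric, train/validation/test fractions summing
#'   to 1 (default `c(0.7, 0.1, 0.2)`).
#' @return list with `train`, `val`, `test` segment lists and a `record`
#'   integer vector per split identifying the source record.
#' @export
split_segments <- function(segments, fractions = c(0.7, 0.1, 0.2)) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 ||
      any(fractions < 0)) {
    stop("'fractions' must be three nonnegative numbers summing to 1")
  }
  per_record <- if (length(segments) > 0 && inherits(segments[[1]], "ppg_segment")) {
    list(segments)
  } else segments
  out <- list(train = list(), val = list(), test = list(),
              record = list(train = integer(0), val = integer(0), test = integer(0)))
  for (r in seq_along(per_record)) {
    segs <- per_record[[r]]
    nseg <- length(segs)
    if (nseg < 2L) {
      stop("record ", r, " has ", nseg,
           " segment(s); at least 2 are needed to split")
    }
    n_train <- floor(fractions[1] * nseg)
    n_val <- floor(fractions[2] * nseg)
    n_test <- nseg - n_train - n_val
    if (n_train < 1L || n_test < 1L) {
      stop("record ", r, ": split of ", nseg,
           " segments leaves an empty train or test set")
    }
    out$train <- c(out$train, segs[seq_len(n_train)])
    if (n_val > 0L) out$val <- c(out$val, segs[n_train + seq_len(n_val)])
    out$test <- c(out$test, segs[n_train + n_val + seq_len(n_test)])
    out$record$train <- c(out$record$train, rep(r, n_train))
    out$record$val <- c(out$record$val, rep(r, n_val))
    out$record$test <- c(out$record$test, rep(r, n_test))
  }
  out
}
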