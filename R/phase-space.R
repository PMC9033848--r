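#' Construct a waveform segment
#'
#' A segment is a short window of a pulse waveform together with its sampling
#' rate and scalar blood-pressure targets. It is the unit every downstream
#' stage (embedding, FRP construction, model training) operates on.
#'
#' @param samples numeric vector of waveform samples (arbitrary amplitude units).
#' @param fs sampling rate in Hz.
#' @param sbp,dbp scalar systolic / diastolic pressure targets in mmHg, or `NA`
#'   when the segment is unlabelled.
#' @return an object of class `ppg_segment`.
#' @export
ppg_segment <- function(samples, fs = 125, sbp = NA_real_, dbp = NA_real_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a segment needs at least 2 samples, got ", length(samples))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive sampling rate in Hz")
  }
  if (!anyNA(c(sbp, dbp)) && sbp <= dbp) {
    stop("systolic pressure must exceed diastolic pressure (got sbp = ",
         sbp, ", dbp = ", dbp, ")")
  }
  structure(
    list(samples = samples, fs = fs, sbp = as.numeric(sbp), dbp = as.numeric(dbp)),
    class = "ppg_segment"
  )
}

#' @export
print.ppg_segment <- function(x, ...) {
  cat(sprintf("<ppg_segment> %d samples @ %g Hz (%.2f s), SBP %s / DBP %s mmHg\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              format(x$sbp), format(x$dbp)))
  invisible(x)
}

#' Delay-embed a segment into phase space
#'
#' Reconstructs the system trajectory of a scalar series by the method of
#' delays: state `p` is `(x_p, x_{p+tau}, ..., x_{p+(m-1)tau})`. A segment of
#' length `L` yields `N = L - (m - 1) * tau` states, kept in temporal order.
#'
#' @param segment a [ppg_segment()] or a bare numeric vector.
#' @param m embedding dimension (default 3).
#' @param tau embedding delay in samples (default 5, i.e. 40 ms at 125 Hz).
#' @return an object of class `phase_trajectory` with fields `states`
#'   (an `N x m` matrix, one state per row), `m`, `tau` and `N`.
#' @examples
#' tr <- embed_trajectory(ppg_segment(sin(seq(0, 20, by = 0.1))), m = 3, tau = 5)
#' dim(tr$states)
#' @export
embed_trajectory <- function(segment, m = 3L, tau = 5L) {
  x <- if (inherits(segment, "ppg_segment")) segment$samples else as.numeric(segment)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L) stop("embedding dimension 'm' must be >= 1")
  if (tau < 1L) stop("embedding delay 'tau' must be >= 1")
  L <- length(x)
  need <- (m - 1L) * tau + 1L
  if (L < need) {
    stop("segment too short for embedding: length ", L,
         " but (m - 1) * tau + 1 = ", need, " samples are required")
  }
  N <- L - (m - 1L) * tau
  states <- matrix(0, nrow = N, ncol = m)
  for (j in seq_len(m)) {
    states[, j] <- x[seq.int(1L + (j - 1L) * tau, length.out = N)]
  }
  structure(list(states = states, m = m, tau = tau, N = N),
            class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory> N = %d states, dimension %d, delay %d\n",
              x$N, x$m, x$tau))
  invisible(x)
}

#' Decimate a trajectory to a fixed number of states
#'
#' Selects `s` states at uniformly spaced indices `round(seq(1, N, length.out = s))`
#' so that the recurrence plot built from the trajectory has a configured side
#' length. This keeps the plot a true state-similarity matrix (no image
#' interpolation); first and last states are always retained.
#'
#' @param traj a `phase_trajectory`.
#' @param s requested number of states, `2 <= s <= N`.
#' @return a `phase_trajectory` with exactly `s` states; the input unchanged
#'   when `s == N`.
#' @export
decimate_trajectory <- function(traj, s) {
  stopifnot(inherits(traj, "phase_trajectory"))
  s <- as.integer(s)
  if (s < 2L) stop("'s' must be at least 2")
  if (s > traj$N) {
    stop("cannot decimate ", traj$N, " states to ", s,
         ": use a longer segment or a smaller target side")
  }
  if (s == traj$N) return(traj)
  idx <- round(seq(1, traj$N, length.out = s))
  structure(list(states = traj$states[idx, , drop = FALSE],
                 m = traj$m, tau = traj$tau, N = s),
            class = "phase_trajectory")
}

#' Read waveform records from CSV
#'
#' Expects a column named `ppg` (the waveform) and optionally `time` (or `index`),
#' `sbp` and `dbp` (per-sample target series). The sampling rate is taken from
#' the `time` column spacing when present, otherwise from `fs`.
#'
#' @param path CSV file path.
#' @param fs fallback sampling rate in Hz when no time column is present.
#' @return a `signal_record`: list with `ppg`, `fs`, and per-sample `sbp`, `dbp`
#'   vectors (NA when absent).
#' @export
read_signal_csv <- function(path, fs = 125) {
  df <- read.csv(path)
  nm <- tolower(names(df))
  names(df) <- nm
  if (!"ppg" %in% nm) stop("CSV must contain a 'ppg' column: ", path)
  if ("time" %in% nm && nrow(df) >= 2L) {
    dt <- diff(df$time[1:2])
    if (is.finite(dt) && dt > 0) fs <- 1 / dt
  }
  n <- nrow(df)
  rec <- list(
    ppg = as.numeric(df$ppg),
    fs = fs,
    sbp = if ("sbp" %in% nm) as.numeric(df$sbp) else rep(NA_real_, n),
    dbp = if ("dbp" %in% nm) as.numeric(df$dbp) else rep(NA_real_, n)
  )
  class(rec) <- "signal_record"
  rec
}

#' Write a waveform record to CSV
#'
#' Inverse of [read_signal_csv()]: one row per sample with `time`, `ppg` and,
#' when labelled, `sbp` / `dbp` columns.
#'
#' @param record a `signal_record` (see [generate_record()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(record, path) {
  n <- length(record$ppg)
  df <- data.frame(time = (seq_len(n) - 1) / record$fs, ppg = record$ppg)
  if (!all(is.na(record$sbp))) df$sbp <- record$sbp
  if (!all(is.na(record$dbp))) df$dbp <- record$dbp
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
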