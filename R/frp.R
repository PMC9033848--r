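# Recurrence plots: the classical thresholded (binary) plot and its fuzzy
# generalisation built from fuzzy c-means memberships by max-min composition.

#' Binary recurrence plot
#'
#' `R[i, j] = 1` iff the Euclidean distance between states `i` and `j` is
#' strictly below the similarity threshold `epsilon` (Heaviside of
#' `epsilon - distance`); the diagonal is therefore all ones for any positive
#' threshold. Kept as the classical baseline the fuzzy plot removes the
#' threshold from.
#'
#' @param traj a `phase_trajectory` (see [embed_trajectory()]) or an `N x d`
#'   state matrix.
#' @param epsilon positive similarity threshold in state-space distance units.
#' @return an `rp_matrix`: list with the binary `N x N` matrix `R` and `epsilon`.
#' @export
binary_rp <- function(traj, epsilon) {
  X <- if (inherits(traj, "phase_trajectory")) traj$states else as.matrix(traj)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("'epsilon' must be a single positive threshold")
  }
  D <- as.matrix(stats::dist(X))
  R <- (D < epsilon) * 1L
  structure(list(R = R, epsilon = epsilon), class = "rp_matrix")
}

#' Fuzzy recurrence plot from a fuzzy partition
#'
#' The similarity between states `i` and `j` is inferred from their cluster
#' memberships by the max-min composition of the fuzzy relation:
#' \deqn{M_{ij} = \max_k \min(\mu_{ik}, \mu_{jk}),}
#' with reflexivity imposed explicitly (`M[i, i] = 1`). The result is a
#' symmetric matrix with entries in `[0, 1]` — a grayscale, threshold-free
#' recurrence plot.
#'
#' @param partition a `fuzzy_partition` from [fcm_fit()], or a bare `N x c`
#'   row-stochastic membership matrix.
#' @return an `frp_matrix`: list with the `N x N` matrix `M`, `side = N`, and
#'   `cluster_count`.
#' @examples
#' U <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
#' fuzzy_rp(U)$M
#' @export
fuzzy_rp <- function(partition) {
  U <- if (inherits(partition, "fuzzy_partition")) partition$U else as.matrix(partition)
  if (any(U < -1e-9) || any(U > 1 + 1e-9)) {
    stop("memberships must lie in [0, 1]")
  }
  if (max(abs(rowSums(U) - 1)) > 1e-6) {
    stop("membership rows must sum to 1")
  }
  N <- nrow(U)
  M <- matrix(0, N, N)
  for (k in seq_len(ncol(U))) {
    uk <- U[, k]
    M <- pmax(M, pmin(matrix(uk, N, N), matrix(uk, N, N, byrow = TRUE)))
  }
  diag(M) <- 1
  structure(list(M = M, side = N,
                 cluster_count = ncol(U)),
            class = "frp_matrix")
}

#' Render a fuzzy recurrence plot as a grayscale image
#'
#' Returns the similarity matrix as image intensities in `[0, 1]`; with
#' `invert = TRUE` the complement `1 - M` is returned so that similar state
#' pairs render dark on a white background. Inversion is a display option only;
#' the network consumes `M` directly.
#'
#' @param frp an `frp_matrix`.
#' @param invert complement the intensities for white-background rendering.
#' @return a numeric matrix of intensities in `[0, 1]`.
#' @export
frp_image <- function(frp, invert = FALSE) {
  stopifnot(inherits(frp, "frp_matrix"))
  if (invert) 1 - frp$M else frp$M
}

#' Export a fuzzy recurrence plot as an 8-bit grayscale PNG
#'
#' Intensities are scaled linearly to 0-255, so a round trip through the file
#' agrees with the matrix to within 1/255 per entry.
#'
#' @inheritParams frp_image
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_frp_png <- function(frp, path, invert = FALSE) {
  img <- frp_image(frp, invert = invert)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Segment to fuzzy recurrence plot
#'
#' The full 1-D-to-2-D conversion: delay embedding, uniform decimation of the
#' trajectory to the requested side, fuzzy c-means clustering of the states,
#' and max-min composition of the memberships. Deterministic for a fixed seed.
#'
#' @param segment a [ppg_segment()] or numeric vector.
#' @param side side length of the plot (number of retained states; default 88).
#' @param m,tau embedding dimension and delay (see [embed_trajectory()]).
#' @param c,omega,alpha,max_iter,seed fuzzy c-means settings (see [fcm_fit()]).
#' @return an `frp_matrix` of size `side x side`.
#' @export
segment_to_frp <- function(segment, side = 88L, m = 3L, tau = 5L,
                           c = 3L, omega = 2, alpha = 1e-5, max_iter = 300L,
                           seed = 1L) {
  traj <- embed_trajectory(segment, m = m, tau = tau)
  traj <- decimate_trajectory(traj, side)
  # constant segments collapse every state onto one point; all-ones plot
  if (max(traj$states) - min(traj$states) == 0) {
    return(structure(list(M = matrix(1, side, side), side = as.integer(side),
                          cluster_count = as.integer(c)),
                     class = "frp_matrix"))
  }
  part <- suppressWarnings(
    fcm_fit(traj, c = c, omega = omega, alpha = alpha,
            max_iter = max_iter, seed = seed)
  )
  fuzzy_rp(part)
}

#' @export
print.frp_matrix <- function(x, ...) {
  off <- x$M[row(x$M) != col(x$M)]
  cat(sprintf("<frp_matrix> %d x %d, %d clusters, mean off-diagonal similarity %.3f\n",
              x$side, x$side, x$cluster_count, mean(off)))
  invisible(x)
}
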