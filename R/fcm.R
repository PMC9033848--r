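# Fuzzy c-means over phase-space states. States are an N x d matrix (one state
# per row); memberships U are N x c and row-stochastic; centers Z are c x d.

# squared Euclidean distances between rows of X (N x d) and rows of Z (c x d)
sq_dist_to_centers <- function(X, Z) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(Z))) +
    outer(rep(1, nrow(X)), rowSums(Z^2)) - 2 * X %*% t(Z)
  pmax(d2, 0)
}

check_fcm_shapes <- function(states, U = NULL, Z = NULL) {
  if (!is.matrix(states)) states <- as.matrix(states)
  if (!is.null(U)) {
    if (!is.matrix(U) || nrow(U) != nrow(states)) {
      stop("membership matrix U must have one row per state")
    }
  }
  if (!is.null(Z)) {
    if (!is.matrix(Z) || ncol(Z) != ncol(states)) {
      stop("cluster centers Z must live in the state space (", ncol(states),
           " columns)")
    }
  }
  states
}

#' Fuzzy c-means objective
#'
#' The weighted within-cluster scatter
#' \deqn{J(U, Z) = \sum_{i=1}^{N} \sum_{k=1}^{c} \mu_{ik}^{\omega}\, d(x_i, z_k)^2}
#' with Euclidean \eqn{d}; fuzzy c-means minimises this under the constraint
#' that each row of \eqn{U} sums to one.
#'
#' @param states `N x d` matrix of phase-space states (rows).
#' @param U `N x c` membership matrix.
#' @param Z `c x d` matrix of cluster centers (rows).
#' @param omega fuzzy weighting exponent, must be > 1 (2 is the usual choice).
#' @return the scalar objective value.
#' @export
fcm_objective <- function(states, U, Z, omega = 2) {
  states <- check_fcm_shapes(states, U, Z)
  if (omega <= 1) stop("fuzzy exponent 'omega' must be > 1")
  if (ncol(U) != nrow(Z)) stop("U has ", ncol(U), " clusters but Z has ", nrow(Z))
  sum(U^omega * sq_dist_to_centers(states, Z))
}

#' Membership update of fuzzy c-means
#'
#' Inverse-distance-ratio update:
#' \deqn{\mu_{ik} = 1 / \sum_j (d(x_i,z_k)/d(x_i,z_j))^{2/(\omega-1)}.}
#' A state coinciding with one or more centers gets a crisp membership of 1 to
#' the first zero-distance cluster and 0 elsewhere.
#'
#' @inheritParams fcm_objective
#' @return `N x c` row-stochastic membership matrix.
#' @export
update_memberships <- function(states, Z, omega = 2) {
  states <- check_fcm_shapes(states, Z = Z)
  if (omega <= 1) stop("fuzzy exponent 'omega' must be > 1")
  if (nrow(Z) < 1L) stop("at least one cluster center is required")
  d2 <- sq_dist_to_centers(states, Z)
  p <- 1 / (omega - 1)
  # mu_ik = (1/d2_ik)^p / sum_j (1/d2_ij)^p  (equivalent to the ratio form)
  inv <- d2^(-p)
  U <- inv / rowSums(inv)
  zero <- d2 <= .Machine$double.eps^2
  hit <- which(rowSums(zero) > 0L)
  for (i in hit) {
    U[i, ] <- 0
    U[i, which(zero[i, ])[1L]] <- 1
  }
  U
}

#' Center update of fuzzy c-means
#'
#' Membership-weighted mean of the states:
#' \deqn{z_j = \sum_i \mu_{ij}^{\omega} x_i \,/\, \sum_i \mu_{ij}^{\omega}.}
#'
#' @inheritParams fcm_objective
#' @return `c x d` matrix of updated centers.
#' @export
update_centers <- function(states, U, omega = 2) {
  states <- check_fcm_shapes(states, U)
  W <- U^omega
  wsum <- colSums(W)
  if (any(wsum <= 0)) {
    stop("degenerate cluster: membership column ", which(wsum <= 0)[1L],
         " has zero total weight")
  }
  sweep(t(W) %*% states, 1, wsum, "/")
}

# center update tolerant of collapsed clusters: a cluster whose memberships
# vanish keeps its previous center (needed for degenerate inputs such as
# constant segments, where all states coincide)
update_centers_safe <- function(states, U, omega, Z_prev) {
  W <- U^omega
  wsum <- colSums(W)
  Z <- Z_prev
  ok <- wsum > .Machine$double.eps
  if (any(ok)) {
    Z[ok, ] <- sweep(t(W[, ok, drop = FALSE]) %*% states, 1, wsum[ok], "/")
  }
  Z
}

#' Fit fuzzy c-means
#'
#' Alternates the center and membership updates from a seeded random
#' row-normalised membership matrix until the maximum absolute elementwise
#' change of `U` falls to `alpha` or below, or `max_iter` is reached. The
#' objective is non-increasing across iterations.
#'
#' @param states `N x d` matrix of states (a `phase_trajectory` is also accepted).
#' @param c number of clusters, `1 <= c <= N` (1 is the degenerate single-cluster
#'   case).
#' @param omega fuzzy weighting exponent (> 1; default 2).
#' @param alpha convergence tolerance on `max |U(t) - U(t+1)|` (default 1e-5).
#' @param max_iter iteration cap (default 300).
#' @param seed integer seed for the random initialisation.
#' @param U_init optional explicit initial membership matrix (overrides `seed`);
#'   rows are renormalised to sum to one.
#' @param trace keep a list of the membership matrices after every iteration
#'   (in `U_trace`), for convergence diagnostics.
#' @return a `fuzzy_partition`: list with `U`, `Z`, `c`, `omega`, `alpha`,
#'   final objective `J`, per-iteration `J_history`, iteration count `iters`,
#'   and a `converged` flag (a non-converged fit is returned with a warning,
#'   not an error).
#' @examples
#' X <- rbind(matrix(rnorm(20, 0, .1), 10), matrix(rnorm(20, 5, .1), 10))
#' fit <- fcm_fit(X, c = 2, seed = 1)
#' round(fit$U[c(1, 15), ], 3)
#' @export
fcm_fit <- function(states, c = 3L, omega = 2, alpha = 1e-5, max_iter = 300L,
                    seed = 1L, U_init = NULL, trace = FALSE) {
  if (inherits(states, "phase_trajectory")) states <- states$states
  states <- check_fcm_shapes(states)
  c <- as.integer(c)
  N <- nrow(states)
  if (c < 1L) stop("'c' must be at least 1")
  if (N < c) stop("cannot form ", c, " clusters from ", N, " states")
  if (omega <= 1) stop("fuzzy exponent 'omega' must be > 1")
  if (alpha <= 0) stop("'alpha' must be a small positive tolerance")

  if (c == 1L) {
    U <- matrix(1, N, 1)
    Z <- matrix(colMeans(states), 1)
    J <- fcm_objective(states, U, Z, omega)
    return(structure(list(U = U, Z = Z, c = c, omega = omega, alpha = alpha,
                          J = J, J_history = J, iters = 0L, converged = TRUE),
                     class = "fuzzy_partition"))
  }

  if (is.null(U_init)) {
    U <- withr_seed_matrix(N, c, seed)
  } else {
    U <- as.matrix(U_init)
    if (!all(dim(U) == c(N, c))) stop("'U_init' must be ", N, " x ", c)
    U <- U / rowSums(U)
  }

  Z <- update_centers(states, U, omega)
  J_hist <- numeric(0)
  U_trace <- if (trace) list() else NULL
  converged <- FALSE
  iters <- 0L
  repeat {
    iters <- iters + 1L
    Z <- update_centers_safe(states, U, omega, Z)
    U_new <- update_memberships(states, Z, omega)
    J_hist[iters] <- fcm_objective(states, U_new, Z, omega)
    if (trace) U_trace[[iters]] <- U_new
    delta <- max(abs(U_new - U))
    U <- U_new
    if (delta <= alpha) { converged <- TRUE; break }
    if (iters >= max_iter) break
  }
  if (!converged) {
    warning("fuzzy c-means did not converge in ", max_iter, " iterations")
  }
  structure(list(U = U, Z = Z, c = c, omega = omega, alpha = alpha,
                 J = J_hist[iters], J_history = J_hist, iters = iters,
                 converged = converged, U_trace = U_trace),
            class = "fuzzy_partition")
}

# seeded uniform random memberships, row-normalised; local RNG scope
withr_seed_matrix <- function(N, c, seed) {
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
  set.seed(seed)
  U <- matrix(runif(N * c), N, c)
  U / rowSums(U)
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> N = %d, c = %d, omega = %g, J = %.6g, %s after %d iterations\n",
              nrow(x$U), x$c, x$omega, x$J,
              if (x$converged) "converged" else "NOT converged", x$iters))
  invisible(x)
}
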