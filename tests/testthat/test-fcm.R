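test_that("objective matches hand and brute-force values", {
  # two 1-D points {0, 2}, one cluster at their mean, full membership
  X <- matrix(c(0, 2))
  expect_equal(fcm_objective(X, matrix(1, 2, 1), matrix(1), omega = 2), 2)

  # states sitting on their centers
  Z <- matrix(c(0, 2))
  U <- diag(2)
  expect_equal(fcm_objective(X, U, Z, omega = 2), 0)

  # random instances against the double-loop oracle
  set.seed(42)
  for (rep in 1:10) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    U <- matrix(runif(8 * 2), 8, 2); U <- U / rowSums(U)
    Z <- matrix(rnorm(2 * 3), 2, 3)
    w <- 1.5 + runif(1)
    expect_equal(fcm_objective(X, U, Z, w), ref_fcm_objective(X, U, Z, w),
                 tolerance = 1e-12)
  }
  expect_error(fcm_objective(X, U, Z, omega = 1), "omega")
})

test_that("membership update reproduces the inverse-distance-ratio rule", {
  # 1-D state at 0 with centers 1 and 3: 1/(1 + (1/3)^2) = 9/10
  U <- update_memberships(matrix(0), matrix(c(1, 3)), omega = 2)
  expect_equal(drop(U), c(0.9, 0.1))

  # equidistant state
  U <- update_memberships(matrix(2), matrix(c(1, 3)), omega = 2)
  expect_equal(drop(U), c(0.5, 0.5))

  # state on a center: crisp assignment
  U <- update_memberships(matrix(c(1)), matrix(c(1, 3)), omega = 2)
  expect_equal(drop(U), c(1, 0))

  # rows always sum to one
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  Z <- matrix(rnorm(12), 4, 3)
  U <- update_memberships(X, Z, omega = 1.7)
  expect_equal(rowSums(U), rep(1, 10), tolerance = 1e-12)
  expect_true(all(U >= 0 & U <= 1))
})

test_that("center update is the membership-weighted mean", {
  X <- matrix(c(0, 2))
  # uniform memberships: arithmetic mean
  expect_equal(drop(update_centers(X, matrix(1, 2, 1), omega = 2)), 1)
  # hand-computed weighted mean: (0 + 0.25 * 2) / 1.25 = 0.4
  expect_equal(drop(update_centers(X, matrix(c(1, 0.5)), omega = 2)), 0.4)
  # brute-force oracle on a random instance
  set.seed(2)
  Xr <- matrix(rnorm(15), 5, 3)
  Ur <- matrix(runif(10), 5, 2); Ur <- Ur / rowSums(Ur)
  Zr <- update_centers(Xr, Ur, omega = 2.2)
  for (j in 1:2) {
    w <- Ur[, j]^2.2
    expect_equal(Zr[j, ], colSums(Xr * w) / sum(w), tolerance = 1e-12)
  }
  expect_error(update_centers(Xr, matrix(0, 5, 2)), "degenerate")
})

test_that("fcm_fit separates well-separated groups and keeps its invariants", {
  set.seed(7)
  X <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2), matrix(rnorm(20, 4, 0.05), 10, 2))
  fit <- fcm_fit(X, c = 2, seed = 3, trace = TRUE)
  expect_true(fit$converged)
  top <- apply(fit$U, 1, max)
  expect_true(all(top >= 0.99))
  # the two groups land in different clusters
  g1 <- which.max(fit$U[1, ]); g2 <- which.max(fit$U[15, ])
  expect_true(g1 != g2)

  # row-stochastic at every iteration; objective non-increasing
  for (U in fit$U_trace) {
    expect_equal(rowSums(U), rep(1, nrow(X)), tolerance = 1e-9)
  }
  expect_true(all(diff(fit$J_history) <= 1e-9))
})

test_that("degenerate cluster counts are handled", {
  X <- matrix(rnorm(10), 5, 2)
  one <- fcm_fit(X, c = 1)
  expect_equal(one$U, matrix(1, 5, 1))
  expect_equal(drop(one$Z), colMeans(X))
  expect_equal(one$J, sum(sweep(X, 2, colMeans(X))^2))
  expect_error(fcm_fit(X, c = 6), "clusters")
})

test_that("relabelling clusters leaves the objective unchanged", {
  set.seed(9)
  X <- matrix(rnorm(24), 8, 3)
  U <- matrix(runif(24), 8, 3); U <- U / rowSums(U)
  Z <- matrix(rnorm(9), 3, 3)
  p <- c(3, 1, 2)
  expect_equal(fcm_objective(X, U, Z, 2),
               fcm_objective(X, U[, p], Z[p, ], 2), tolerance = 1e-12)
})

test_that("non-convergence is flagged with a warning, not an error", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  expect_warning(fit <- fcm_fit(X, c = 3, alpha = 1e-12, max_iter = 2),
                 "did not converge")
  expect_false(fit$converged)
  expect_s3_class(fit, "fuzzy_partition")
})
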