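test_that("binary recurrence plot thresholds pairwise distances", {
  tr <- embed_trajectory(c(0, 1, 3), m = 1, tau = 1)
  rp <- binary_rp(tr, epsilon = 1.5)
  expect_equal(rp$R, rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)),
               ignore_attr = TRUE)

  X <- matrix(rnorm(20), 10, 2)
  all1 <- binary_rp(X, epsilon = max(dist(X)) + 1)
  expect_true(all(all1$R == 1))
  tiny <- binary_rp(X, epsilon = 1e-12)
  expect_equal(tiny$R, diag(10), ignore_attr = TRUE)
  expect_error(binary_rp(X, epsilon = 0), "positive")
})

test_that("binary plot is invariant under isometries of the state space", {
  set.seed(11)
  X <- matrix(rnorm(30), 15, 2)
  theta <- 0.7
  Q <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  Xr <- X %*% Q + matrix(c(3, -1), 15, 2, byrow = TRUE)
  expect_equal(binary_rp(X, 1)$R, binary_rp(Xr, 1)$R, tolerance = 0)
})

test_that("max-min composition matches hand values and is reflexive/symmetric", {
  U <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  M <- fuzzy_rp(U)$M
  expect_equal(diag(M), rep(1, 3))
  expect_equal(M[1, 2], 0)
  expect_equal(M[1, 3], 0.5)
  expect_equal(M[2, 3], 0.5)
  expect_equal(M, t(M))

  # crisp one-hot memberships give a block-structured binary plot
  lab <- c(1, 2, 1, 2, 2)
  Uc <- matrix(0, 5, 2); Uc[cbind(1:5, lab)] <- 1
  Mc <- fuzzy_rp(Uc)$M
  expect_equal(Mc, (outer(lab, lab, "==")) * 1, ignore_attr = TRUE)
})

test_that("fuzzy plot equals the brute-force triple loop and ignores relabelling", {
  set.seed(21)
  for (rep in 1:25) {
    N <- sample(2:30, 1)
    c <- sample(2:5, 1)
    U <- matrix(runif(N * c), N, c); U <- U / rowSums(U)
    M <- fuzzy_rp(U)$M
    expect_equal(M, ref_maxmin(U), tolerance = 0)
    p <- sample(c)
    expect_equal(fuzzy_rp(U[, p])$M, M, tolerance = 0)
  }
})

test_that("image rendering and PNG export behave", {
  U <- matrix(runif(40), 20, 2); U <- U / rowSums(U)
  frp <- fuzzy_rp(U)
  img <- frp_image(frp)
  expect_identical(img, frp$M)
  inv <- frp_image(frp, invert = TRUE)
  expect_equal(inv, 1 - frp$M)
  expect_equal(diag(frp_image(fuzzy_rp(diag(3)), invert = TRUE)), rep(0, 3))

  path <- withr::local_tempfile(fileext = ".png")
  write_frp_png(frp, path)
  back <- png::readPNG(path)
  expect_lte(max(abs(back - frp$M)), 1 / 255)
})

test_that("segment_to_frp composes the stages deterministically", {
  seg <- ppg_segment(rep(1, 300))
  M <- segment_to_frp(seg, side = 40)$M
  expect_true(all(M == 1))

  rec <- generate_record(generator_config(duration = 10, seed = 8))
  seg <- segment_record(rec, window = 512)[[1]]
  a <- segment_to_frp(seg, side = 48, seed = 2)
  b <- segment_to_frp(seg, side = 48, seed = 2)
  expect_identical(a$M, b$M)
  expect_equal(dim(a$M), c(48, 48))
  expect_true(all(a$M >= 0 & a$M <= 1))
  expect_equal(a$M, t(a$M), tolerance = 1e-12)
})

test_that("periodic signals are more self-similar than white noise", {
  set.seed(31)
  periodic <- generate_record(generator_config(duration = 10, seed = 9,
                                               noise_sd = 0, hr_sd = 0,
                                               sbp_step_sd = 0, dbp_step_sd = 0,
                                               wander_amp = 0))
  seg_p <- segment_record(periodic, window = 512)[[1]]
  seg_n <- ppg_segment(rnorm(512), fs = 125)
  mean_off <- function(M) mean(M[row(M) != col(M)])
  m_p <- mean_off(segment_to_frp(seg_p, side = 64, seed = 3)$M)
  m_n <- mean_off(segment_to_frp(seg_n, side = 64, seed = 3)$M)
  expect_gt(m_p, m_n)
})
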