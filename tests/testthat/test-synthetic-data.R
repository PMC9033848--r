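test_that("noiseless constant-BP records are exactly periodic", {
  cfg <- generator_config(duration = 10, hr_mean = 75, hr_sd = 0,
                          sbp_step_sd = 0, dbp_step_sd = 0,
                          noise_sd = 0, wander_amp = 0, seed = 1)
  rec <- generate_record(cfg)
  period <- round(125 * 60 / 75)
  x <- rec$ppg
  n <- length(x)
  expect_equal(x[1:(n - period)], x[(period + 1):n], tolerance = 1e-12)

  # beat count by onset count: 12.5 beats in 10 s -> 12 or 13 onsets
  expect_true(length(rec$onsets) %in% c(12, 13))

  # constant-BP labels are constant
  expect_equal(unique(rec$sbp), 120)
  expect_equal(unique(rec$dbp), 80)
})

test_that("generation is bitwise reproducible and leaves the RNG alone", {
  cfg <- generator_config(duration = 8, seed = 99)
  set.seed(1); before <- rnorm(1)
  a <- generate_record(cfg)
  b <- generate_record(cfg)
  expect_identical(a$ppg, b$ppg)
  expect_identical(a$sbp, b$sbp)
  set.seed(1); expect_identical(rnorm(1), before)
})

test_that("SBP labels respect the configured bounds across many seeds", {
  for (s in 1:100) {
    rec <- generate_record(generator_config(duration = 4, seed = s,
                                            sbp_step_sd = 12,
                                            dbp_step_sd = 9))
    expect_true(all(rec$sbp >= 95 & rec$sbp <= 180))
    expect_true(all(rec$dbp >= 50 & rec$dbp <= 90))
    expect_true(all(rec$sbp > rec$dbp))
  }
})

test_that("morphology follows the pressures monotonically", {
  mk <- function(sbp) {
    generate_record(generator_config(duration = 6, seed = 5, hr_sd = 0,
                                     sbp_start = sbp, sbp_step_sd = 0,
                                     dbp_step_sd = 0, noise_sd = 0,
                                     wander_amp = 0))
  }
  lo <- mk(100); hi <- mk(170)
  expect_gt(max(hi$ppg), max(lo$ppg))
})

test_that("windowing counts and labels are correct", {
  rec <- generate_record(generator_config(duration = 8, seed = 2))
  L <- length(rec$ppg)  # 1000 samples
  segs <- segment_record(rec, window = 200, stride = 200)
  expect_length(segs, 5)
  one <- segment_record(rec, window = L)
  expect_length(one, 1)
  expect_equal(one[[1]]$sbp, mean(rec$sbp))

  const <- generate_record(generator_config(duration = 8, seed = 2,
                                            sbp_step_sd = 0, dbp_step_sd = 0))
  seg <- segment_record(const, window = 250)[[1]]
  expect_equal(seg$sbp, 120)
  expect_error(segment_record(rec, window = L + 1), "shorter than the window")
})

test_that("chronological split uses floor counts with remainder to test", {
  segs <- replicate(100, ppg_segment(rnorm(16)), simplify = FALSE)
  sp <- split_segments(segs)
  expect_equal(lengths(sp[c("train", "val", "test")]), c(train = 70, val = 10, test = 20))

  sp10 <- split_segments(segs[1:10])
  expect_equal(lengths(sp10[c("train", "val", "test")]), c(train = 7, val = 1, test = 2))

  expect_error(split_segments(segs[1]), "at least 2")

  # chronological: train indices precede val precede test within the record
  idx <- vapply(segs, function(s) s$samples[1], numeric(1))
  expect_identical(vapply(sp$train, function(s) s$samples[1], numeric(1)), idx[1:70])
  expect_identical(vapply(sp$test, function(s) s$samples[1], numeric(1)), idx[81:100])
})

test_that("segments of one record never cross splits", {
  per_rec <- make_segments(n_records = 3, duration = 30, window = 250, seed = 7)
  sp <- split_segments(per_rec)
  n_all <- sum(lengths(per_rec))
  expect_equal(length(sp$train) + length(sp$val) + length(sp$test), n_all)
  # tag segments by identity (sample vectors are unique with noise on)
  key <- function(s) paste(signif(s$samples[1:5], 12), collapse = ",")
  keys <- c(vapply(sp$train, key, ""), vapply(sp$val, key, ""),
            vapply(sp$test, key, ""))
  expect_equal(anyDuplicated(keys), 0)
})

test_that("noise weakens recurrence texture monotonically", {
  mean_off <- function(M) mean(M[row(M) != col(M)])
  vals <- vapply(c(0, 0.15, 0.6), function(ns) {
    rec <- generate_record(generator_config(duration = 10, seed = 12,
                                            noise_sd = ns, hr_sd = 0,
                                            sbp_step_sd = 0, dbp_step_sd = 0,
                                            wander_amp = 0))
    seg <- segment_record(rec, window = 512)[[1]]
    mean_off(segment_to_frp(seg, side = 64, seed = 4)$M)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})
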