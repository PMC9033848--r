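test_that("fusion operators reproduce hand values", {
  a <- c(1, 2); b <- c(3, 4)
  expect_equal(drop(fuse(a, b, "sum")), c(4, 6))
  expect_equal(drop(fuse(a, b, "max")), c(3, 4))
  expect_equal(drop(fuse(a, b, "concat")), c(1, 2, 3, 4))
  # max fusion is idempotent
  expect_equal(fuse(a, a, "max"), fuse(a, a, "max"))
  expect_equal(drop(fuse(a, a, "max")), a)
  # conv fusion with a filter bank selecting the first N channels returns a
  f <- array(0, c(1, 1, 4, 2)); f[1, 1, 1, 1] <- 1; f[1, 1, 2, 2] <- 1
  expect_equal(drop(fuse(a, b, "conv", f = f)), a)
  # shape mismatches name both shapes
  expect_error(fuse(array(1, c(2, 2, 1)), array(1, c(3, 3, 1)), "sum"),
               "2x2x1.*3x3x1")
})

test_that("fusion operators match brute-force elementwise loops", {
  set.seed(70)
  for (rep in 1:40) {
    H <- sample(1:4, 1); W <- sample(1:4, 1); N <- sample(1:3, 1)
    a <- array(rnorm(H * W * N), c(H, W, N))
    b <- array(rnorm(H * W * N), c(H, W, N))
    s <- fuse(a, b, "sum"); mx <- fuse(a, b, "max"); ct <- fuse(a, b, "concat")
    f <- array(rnorm(2 * N * N), c(1, 1, 2 * N, N)); bias <- rnorm(N)
    cv <- fuse(a, b, "conv", f = f, bias = bias)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      for (n in seq_len(N)) {
        expect_identical(s[i, j, n], a[i, j, n] + b[i, j, n])
        expect_identical(mx[i, j, n], max(a[i, j, n], b[i, j, n]))
        expect_identical(ct[i, j, n], a[i, j, n])
        expect_identical(ct[i, j, N + n], b[i, j, n])
        stacked <- c(a[i, j, ], b[i, j, ])
        expect_equal(cv[i, j, n], sum(stacked * f[1, 1, , n]) + bias[n],
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("the 1-D stream uses kernel length 25 throughout", {
  specs <- build_1d_stream()
  convs <- Filter(function(s) s$kind == "conv1d", specs)
  expect_length(convs, 6)
  expect_true(all(vapply(convs, function(s) s$kernel, numeric(1)) == 25))
  expect_equal(vapply(convs, function(s) s$filters, numeric(1)),
               c(32, 32, 64, 64, 128, 128))
  # flattened width matches the independent shape calculator
  expect_equal(stream_output_shape(specs),
               ref_stream_shape(specs, c(1024, 1)))
  expect_error(build_1d_stream(list(filters = c(0, 8))), "positive")
  expect_error(build_1d_stream(list(window = 8)), "collapses")
})

test_that("the 2-D stream has exactly 7 conv layers and 5 poolings", {
  specs <- build_2d_stream()
  convs <- Filter(function(s) s$kind == "conv2d", specs)
  pools <- Filter(function(s) s$kind == "avgpool", specs)
  expect_length(convs, 7)
  expect_length(pools, 5)
  # spatial floor chain 88 -> 44 -> 22 -> 11 -> 5 -> 2
  shape <- c(88, 88, 1)
  sides <- c()
  for (sp in specs) {
    shape <- stream_output_shape(list(sp), shape)
    if (sp$kind == "avgpool") sides <- c(sides, shape[1])
  }
  expect_equal(sides, c(44, 22, 11, 5, 2))
  expect_equal(stream_output_shape(specs), ref_stream_shape(specs, c(88, 88, 1)))
  expect_error(build_2d_stream(list(side = 16)), "side >= 32")
})

test_that("shape propagation matches the independent calculator on random configs", {
  set.seed(71)
  for (rep in 1:10) {
    nb <- sample(2:4, 1)
    cfg <- list(window = sample(c(128, 256, 512), 1),
                filters = sample(2:8, nb, replace = TRUE),
                kernel = sample(c(3, 9, 25), 1),
                pool_after = seq_len(sample(1:nb, 1)),
                dropout_after = integer(0))
    specs <- build_1d_stream(cfg)
    expect_equal(stream_output_shape(specs),
                 ref_stream_shape(specs, c(cfg$window, 1)))
  }
})

test_that("the concat model spec matches the reference architecture", {
  spec <- build_concat_model()
  expect_equal(spec$fusion, "concat")
  expect_equal(spec$target, "sbp")
  head_dense <- Filter(function(s) s$kind == "dense", spec$head)
  expect_equal(vapply(head_dense, function(s) s$units, numeric(1)), c(256, 64, 1))
  # parameter count of the fused model contains both streams' conv parameters
  pc <- count_parameters(spec)
  expect_gte(pc["total"], pc["stream_1d"] + pc["stream_2d"])
  # separate models per target
  expect_equal(build_model_spec("concat", list(target = "dbp"))$target, "dbp")
  expect_error(build_model_spec("concat", list(fusion = "sum")), "matching")
  expect_error(build_model_spec("concat", list(fusion = "nope")), "fusion")
})

small_1d_cfg <- list(
  window = 128L, side = 32L,
  stream_1d = list(filters = c(4L, 4L, 8L, 8L, 16L, 16L)),
  stream_2d = list(filters = c(4L, 4L, 8L, 8L, 8L, 16L, 16L))
)

test_that("a two-epoch smoke run trains and records history", {
  ds <- make_tiny_dataset(n_records = 2, duration = 35, window = 128, seed = 15)
  tr <- list(x1 = ds$x1[1:48, ], y = ds$y[1:48])
  va <- list(x1 = ds$x1[49:64, ], y = ds$y[49:64])
  spec <- build_model_spec("cnn1d", small_1d_cfg)
  m <- train_model(spec, tr, va, hyper = list(batch = 16, max_epochs = 2,
                                              patience = 5, seed = 1))
  expect_equal(nrow(m$history), 2)
  expect_true(all(is.finite(m$history$val_loss)))

  # same seed -> identical history
  m2 <- train_model(spec, tr, va, hyper = list(batch = 16, max_epochs = 2,
                                               patience = 5, seed = 1))
  expect_identical(m$history, m2$history)

  expect_error(train_model(spec, list(x1 = NULL, y = numeric(0)), va),
               "empty")
})

test_that("training beats the mean predictor and responds to pressure", {
  ds <- make_tiny_dataset(n_records = 3, duration = 70, window = 128, seed = 23)
  n <- length(ds$y)
  itr <- 1:floor(0.7 * n); iva <- (max(itr) + 1):floor(0.85 * n)
  ite <- (floor(0.85 * n) + 1):n
  tr <- list(x1 = ds$x1[itr, ], y = ds$y[itr])
  va <- list(x1 = ds$x1[iva, ], y = ds$y[iva])
  spec <- build_model_spec("cnn1d", small_1d_cfg)
  m <- train_model(spec, tr, va, hyper = list(batch = 32, max_epochs = 10,
                                              patience = 10, seed = 2))
  yhat <- predict(m, ds$x1[ite, ])
  mae <- mean(abs(ds$y[ite] - yhat))
  base <- mean(abs(ds$y[ite] - mean(tr$y)))
  expect_lt(mae, base)

  # monotone response: clearly low- vs high-SBP segments
  lo <- generate_record(generator_config(duration = 4, seed = 3, sbp_start = 100,
                                         sbp_step_sd = 0, dbp_step_sd = 0, hr_sd = 0))
  hi <- generate_record(generator_config(duration = 4, seed = 3, sbp_start = 170,
                                         sbp_step_sd = 0, dbp_step_sd = 0, hr_sd = 0))
  p_lo <- predict(m, segment_record(lo, 128)[[1]]$samples)
  p_hi <- predict(m, segment_record(hi, 128)[[1]]$samples)
  expect_gt(p_hi, p_lo)

  # batch-of-one equals the batched prediction
  expect_equal(predict(m, ds$x1[ite[1], ]), yhat[1], tolerance = 1e-10)

  # save -> load reproduces predictions
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m_back <- load_model(path)
  expect_equal(predict(m_back, ds$x1[ite, ]), yhat, tolerance = 1e-6)
})

test_that("non-finite losses abort with a diagnostic", {
  ds <- make_tiny_dataset(n_records = 2, duration = 20, window = 128, seed = 31)
  tr <- list(x1 = ds$x1, y = ds$y)
  tr$x1[1, 1] <- Inf   # a corrupted sample must not poison training silently
  spec <- build_model_spec("cnn1d", small_1d_cfg)
  expect_error(
    train_model(spec, tr, tr, hyper = list(batch = nrow(tr$x1),
                                           max_epochs = 3, seed = 1)),
    "non-finite loss")
})
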