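test_that("resampling a constant-RR record returns the constant everywhere", {
  rr <- rr_series(rep(0.8, 10))
  x <- resample_uniform(rr, rate = 4)
  expect_s3_class(x, "uniform_hrv")
  expect_true(all(abs(x$values - 0.8) < 1e-12))
  expect_equal(x$rate, 4)
  expect_equal(x$start_time, 0.8) # grid starts at the first beat time
})

test_that("resampling a linear RR drift is monotone and both methods agree", {
  rr <- rr_series(seq(0.8, 1.0, length.out = 20))
  for (method in c("spline", "linear")) {
    x <- resample_uniform(rr, rate = 4, method = method)
    expect_true(all(diff(x$values) >= -1e-12), info = method)
  }
})

test_that("resampling rejects fewer than 2 beats", {
  expect_error(resample_uniform(rr_series(0.8)), "at least 2 beats")
})

test_that("outlier replacement follows the in-IQR median rule", {
  # hand-computed: type-7 quartiles of {0.8 x4, 5.0} are Q1 = Q3 = 0.8, so
  # 5.0 > 1.5 * Q3 = 1.2 is flagged and replaced by median of in-IQR values
  expect_equal(replace_outliers(c(0.8, 0.8, 0.8, 5.0, 0.8)),
               rep(0.8, 5))
  # no spread, no outliers
  expect_equal(replace_outliers(rep(0.8, 5)), rep(0.8, 5))
  # uniform_hrv in, uniform_hrv out, length preserved
  x <- uniform_hrv(c(0.8, 0.82, 0.78, 3.0, 0.81, 0.79), 4)
  y <- replace_outliers(x)
  expect_s3_class(y, "uniform_hrv")
  expect_length(y$values, 6)
  expect_lt(max(y$values), 1)
})

test_that("tukey fences flag the same indices under negation", {
  set.seed(11)
  for (i in 1:20) {
    v <- c(rnorm(20, 0.8, 0.02), 1.6)[sample(21)]
    flagged <- which(replace_outliers(v, fence = "tukey") != v)
    flagged_neg <- which(replace_outliers(-v, fence = "tukey") != -v)
    expect_equal(flagged, flagged_neg)
  }
})

test_that("outlier replacement is idempotent", {
  set.seed(12)
  for (i in 1:20) {
    v <- c(rnorm(30, 0.8, 0.03), runif(2, 1.5, 3))
    for (fence in c("multiplicative", "tukey")) {
      once <- replace_outliers(v, fence = fence)
      expect_equal(replace_outliers(once, fence = fence), once)
    }
  }
})

test_that("coarse-graining computes nonoverlapping block means", {
  expect_equal(coarse_grain(c(2, 4, 6, 8, 10, 12), 3), c(4, 10))
  v <- rnorm(17)
  expect_equal(coarse_grain(v, 1), v)                      # identity at tau=1
  expect_length(coarse_grain(rep(1, 240), 7), 34)          # trailing dropped
  expect_error(coarse_grain(rnorm(5), 6), "exceeds")
})

test_that("coarse-graining preserves the mean when tau divides N and composes", {
  set.seed(13)
  for (i in 1:10) {
    v <- rnorm(60)
    expect_equal(mean(coarse_grain(v, 5)), mean(v))
    expect_equal(coarse_grain(coarse_grain(v, 2), 3), coarse_grain(v, 6))
  }
})

test_that("coarse-graining updates scale and rate metadata", {
  x <- uniform_hrv(rnorm(240, 0.8, 0.02), rate = 4)
  y <- coarse_grain(x, 7)
  expect_equal(y$scale, 7L)
  expect_equal(y$rate, 4 / 7)
  expect_length(y$values, 34)
})

test_that("sliding windows enumerate half-open intervals and drop partials", {
  rec15 <- uniform_hrv(rnorm(60, 0.8, 0.01), 4)   # 15-s record
  w <- sliding_windows(rec15, window_spec(10, 1))
  expect_length(w, 6)
  expect_equal(sapply(w, function(z) z$start_time), 0:5)
  expect_true(all(sapply(w, length) == 40))

  rec10 <- uniform_hrv(rnorm(40, 0.8, 0.01), 4)
  expect_length(sliding_windows(rec10, window_spec(10, 1)), 1)

  rec9 <- uniform_hrv(rnorm(36, 0.8, 0.01), 4)
  expect_warning(w0 <- sliding_windows(rec9, window_spec(10, 1)), "shorter")
  expect_length(w0, 0)
})

test_that("RR series validates invariants", {
  expect_error(rr_series(c(0.8, -0.1)), "positive")
  expect_error(rr_series(c(0.8, 0.9), beat_times = c(1, 1)), "increasing")
  expect_error(rr_series(c(0.8, 0.9), beat_times = c(0.8, 2.5)),
               "inconsistent")
  # offset start times are fine as long as gaps match the intervals
  rr <- rr_series(c(0.8, 0.9, 1.0), beat_times = c(10, 10.9, 11.9))
  expect_equal(rr$beat_times[1], 10)
})

test_that("RR round-trips through the CSV and plain-text readers", {
  rr <- simulate_rr(sim_spec(duration = 30, seed = 4))
  csv <- tempfile(fileext = ".csv")
  write_rr(rr, csv)
  back <- read_rr(csv)
  expect_equal(back$intervals, rr$intervals, tolerance = 1e-9)
  expect_equal(back$beat_times, rr$beat_times, tolerance = 1e-9)

  txt <- tempfile(fileext = ".txt")
  writeLines(c("# comment", format(rr$intervals, digits = 12)), txt)
  back2 <- read_rr(txt)
  expect_equal(back2$intervals, rr$intervals, tolerance = 1e-9)

  # ms column auto-converts
  ms <- tempfile(fileext = ".csv")
  write.csv(data.frame(rr_ms = rr$intervals * 1000), ms, row.names = FALSE)
  expect_equal(read_rr(ms)$intervals, rr$intervals, tolerance = 1e-9)
})
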