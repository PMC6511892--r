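test_that("heart rate is the mean instantaneous rate", {
  expect_equal(heart_rate(rep(0.8, 40)), 75)
  expect_equal(heart_rate(rep(1.0, 40)), 60)
  expect_equal(heart_rate(c(0.5, 1.0)), 90)   # not 60 / mean(x) = 80
  expect_error(heart_rate(c(0.8, 0)), "nonpositive")
})

test_that("SDNN is the sample standard deviation in milliseconds", {
  expect_equal(sdnn(c(0.8, 0.9, 1.0)), 100)
  expect_equal(sdnn(rep(0.8, 10)), 0)
  v <- rnorm(50, 0.8, 0.05)
  expect_equal(sdnn(v), sdnn(v + 0.1))            # shift invariance
  expect_equal(sdnn(2 * v), 2 * sdnn(v))          # linear scaling
  expect_equal(sdnn(v), sdnn(rev(v)))             # order invariance
  expect_equal(heart_rate(v), heart_rate(sample(v)))
  expect_error(sdnn(0.8), "at least 2")
})

test_that("a pure in-band sinusoid recovers its A^2/2 power", {
  fx <- fixture_library()
  sp <- hrv_periodogram(fx$sin_lf)
  total <- pracma::trapz(sp$freqs, sp$power)
  expect_equal(total, 0.05^2 / 2, tolerance = 0.02)
  # demeaned constant signal has essentially no power anywhere
  spc <- hrv_periodogram(uniform_hrv(rep(0.8, 256), 4))
  expect_lt(max(spc$power), 1e-25)
})

test_that("white-noise periodograms average to the flat variance level", {
  set.seed(31)
  sigma <- 0.05
  totals <- replicate(100, {
    sp <- hrv_periodogram(uniform_hrv(rnorm(256, 0.8, sigma), 4))
    pracma::trapz(sp$freqs, sp$power)
  })
  expect_equal(mean(totals), sigma^2, tolerance = 0.05)
})

test_that("band powers land in the right bands and normalize to percent", {
  fx <- fixture_library()
  lf <- band_powers(hrv_periodogram(fx$sin_lf))
  expect_gt(lf$nlf, 98); expect_lt(lf$nhf, 2)
  hf <- band_powers(hrv_periodogram(fx$sin_hf))
  expect_gt(hf$nhf, 98); expect_lt(hf$nlf, 2)
  mix <- band_powers(hrv_periodogram(fx$sin_lf_hf))
  expect_equal(mix$nlf, 50, tolerance = 0.04)
  expect_equal(mix$nhf, 50, tolerance = 0.04)
  expect_lte(mix$alf + mix$ahf, mix$np * (1 + 1e-9))
  # degenerate: no power at all
  flat <- band_powers(hrv_periodogram(uniform_hrv(rep(0.8, 256), 4)))
  expect_true(is.na(flat$nlf) || flat$np < 1e-20)
})

test_that("sample entropy matches hand-analyzed degenerate cases", {
  expect_equal(sample_entropy(rep(c(1, 2), 50), m = 2), 0)
  cst <- sample_entropy(rep(0.8, 50), m = 2)
  expect_true(is.na(cst))
  expect_match(attr(cst, "flag"), "tolerance")
  # any forced positive tolerance on a constant gives perfect regularity
  expect_equal(sample_entropy(rep(0.8, 50), m = 2, r = 0.1), 0)
})

test_that("sample entropy of noise exceeds that of its sorted version", {
  set.seed(32)
  v <- runif(200)
  r <- 0.15 * sd(v)
  expect_gt(sample_entropy(v, m = 2, r = r),
            sample_entropy(sort(v), m = 2, r = r))
})

test_that("sample entropy equals the naive template-count oracle", {
  set.seed(33)
  for (n in c(30, 80, 150)) {
    v <- rnorm(n, 0.8, 0.05)
    r <- 0.2 * sd(v)
    expect_identical(as.numeric(sample_entropy(v, m = 2, r = r)),
                     naive_sample_entropy(v, 2, r))
    expect_identical(as.numeric(sample_entropy(v, m = 3, r = r)),
                     naive_sample_entropy(v, 3, r))
  }
})

test_that("permutation entropy spans its [0, 1] range on extreme inputs", {
  expect_equal(permutation_entropy(1:60, m = 3), 0)   # single pattern
  expect_equal(permutation_entropy(seq(5, 1, length.out = 40), m = 4), 0)
  # frozen search result: the 6 windows realize all 3! patterns exactly once
  expect_equal(permutation_entropy(c(1, 2, 6, 5, 4, 8, 3, 7), m = 3), 1)
})

test_that("permutation entropy is invariant to monotone affine maps", {
  set.seed(34)
  v <- rnorm(150)
  expect_equal(permutation_entropy(v, m = 4),
               permutation_entropy(2 * v + 5, m = 4))
  expect_equal(sample_entropy(v, m = 2, r = 0.2 * sd(v)),
               sample_entropy(v + 3, m = 2, r = 0.2 * sd(v)))
})

test_that("permutation entropy matches the brute-force pattern tally", {
  set.seed(35)
  for (i in 1:10) {
    v <- round(rnorm(120), 2)  # rounding provokes ties
    for (m in 3:5) {
      expect_equal(permutation_entropy(v, m = m),
                   naive_permutation_entropy(v, m))
    }
  }
})

test_that("permutation entropy warns when m! exceeds the window", {
  expect_warning(permutation_entropy(rnorm(100), m = 6), "exceeds")
  expect_silent(permutation_entropy(rnorm(800), m = 6))
})

test_that("the traditional wrapper returns all eight measures", {
  rr <- simulate_rr(sim_spec(duration = 330, seed = 36))
  x <- resample_uniform(rr, 4)
  w <- uniform_hrv(x$values[1:1200], 4)
  tm <- traditional_metrics(w)
  expect_named(tm, c("hr", "sdnn", "alf", "ahf", "nlf", "nhf", "se", "pe"))
  expect_gt(tm$hr, 0)
  expect_gte(tm$pe, 0); expect_lte(tm$pe, 1)
})
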