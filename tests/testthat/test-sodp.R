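test_that("three-point forward derivative matches hand-computed cases", {
  expect_equal(three_point_forward_diff(1:10), rep(1, 8))   # exact on linear
  expect_equal(three_point_forward_diff(c(0, 1, 0, 1, 0, 1)),
               c(2, -2, 2, -2))
  expect_equal(three_point_forward_diff(rep(0.8, 6)), rep(0, 4))
  expect_error(three_point_forward_diff(1:3), "at least 4")
})

test_that("the SODP of a linear ramp collapses to one diagonal point", {
  s <- build_sodp(1:40)
  expect_equal(nrow(s$points), 37)          # N - 3 points
  expect_true(all(s$points$x == 1 & s$points$y == 1))
  expect_true(all(s$angles == 45))
  expect_true(all(s$quadrants == "Q1"))
  expect_equal(s$n_source, 40)

  sneg <- build_sodp(-(1:40))
  expect_true(all(sneg$angles == 225))
  expect_true(all(sneg$quadrants == "Q3"))
})

test_that("alternating input lands on the anti-diagonal with exact angles", {
  s <- build_sodp(c(0, 1, 0, 1, 0, 1))
  expect_equal(s$points$x, c(2, -2, 2))
  expect_equal(s$points$y, c(-2, 2, -2))
  expect_equal(s$quadrants, c("Q4", "Q2", "Q4"))
  expect_equal(s$angles, c(315, 135, 315))
})

test_that("RAS divides the angle sum by the window sample count", {
  expect_equal(real_angle_sum(build_sodp(1:40)), 37 * 45 / 40)    # 41.625
  expect_equal(real_angle_sum(build_sodp(-(1:40))), 37 * 225 / 40) # 208.125
  # denominator switch: divide by the N - 3 points instead
  expect_equal(real_angle_sum(build_sodp(1:40), denominator = "points"), 45)
  ras0 <- real_angle_sum(build_sodp(rep(0.8, 40)))
  expect_equal(as.numeric(ras0), 0)
  expect_true(attr(ras0, "degenerate"))
})

test_that("quadrant proportions count strict-sign points over N", {
  p <- quadrant_proportions(build_sodp(1:40))
  expect_equal(as.numeric(p), c(37 / 40, 0, 0))
  p2 <- quadrant_proportions(build_sodp(rep(c(0, 1), 20)))
  expect_equal(as.numeric(p2), c(0, 37 / 40, 0))
  p3 <- quadrant_proportions(build_sodp(rep(0.8, 40)))
  expect_equal(as.numeric(p3), c(0, 0, 0))   # all points at the origin
})

test_that("axis points keep their exact angle but join no quadrant", {
  # d = (1, 0, -1, 0, 1, ...) pattern via a crafted sequence:
  # points with one zero coordinate are BOUNDARY yet contribute 0/90/180/270
  s <- build_sodp(c(0, 1, 2, 2, 1, 0, 0, 1, 2))
  onaxis <- (s$points$x == 0) != (s$points$y == 0)  # one coord zero
  expect_true(all(s$quadrants[onaxis] == "BOUNDARY"))
  expect_true(all(s$angles[onaxis] %in% c(0, 90, 180, 270)))
  orig <- s$points$x == 0 & s$points$y == 0
  expect_true(all(is.na(s$angles[orig])))
})

test_that("classa_window combines both temporal scales at the printed sizes", {
  x10 <- uniform_hrv(0.8 + 0.001 * (1:40), 4)
  x60 <- uniform_hrv(0.9 - 0.0005 * (1:240), 4)
  res <- classa_window(x10, x60, tau = 7)
  expect_equal(res$n_scale1, 40)
  expect_equal(res$n_scale_tau, 34)
  # coarse-graining a strictly decreasing ramp stays strictly decreasing:
  # every coarse SODP point falls in Q3
  expect_equal(res$pq3, (34 - 3) / 34)
  expect_equal(res$pq1, 37 / 40)
  expect_error(classa_window(uniform_hrv(1:3, 4), x60), "too short")
  expect_error(classa_window(x10, uniform_hrv(1:20, 4), tau = 7),
               "coarse-graining")
})

test_that("metrics are shift-invariant and positive-scale-invariant", {
  set.seed(21)
  for (i in 1:25) {
    # dyadic values make the shift and power-of-two scaling exact in
    # floating point, so the invariance is bit-for-bit
    v <- dyadic_window(sample(10:50, 1))
    s <- build_sodp(v)
    for (w in list(v + 0.5, v * 2)) {
      s2 <- build_sodp(w)
      expect_identical(s2$angles, s$angles)
      expect_identical(s2$quadrants, s$quadrants)
      expect_identical(real_angle_sum(s2), real_angle_sum(s))
      expect_identical(quadrant_proportions(s2), quadrant_proportions(s))
    }
    # a generic shift cancels only to rounding; angles agree to 1e-9 degrees
    s3 <- build_sodp(v + 0.123)
    expect_equal(s3$angles, s$angles, tolerance = 1e-9)
  }
})

test_that("negation reflects the SODP through the origin and swaps quadrants", {
  set.seed(22)
  for (i in 1:25) {
    v <- random_window(sample(10:50, 1))
    s <- build_sodp(v)
    sn <- build_sodp(-v)
    expect_equal(sn$points$x, -s$points$x)
    expect_equal(sn$points$y, -s$points$y)
    tab <- table(factor(s$quadrants, c("Q1", "Q2", "Q3", "Q4", "BOUNDARY")))
    tabn <- table(factor(sn$quadrants, c("Q1", "Q2", "Q3", "Q4", "BOUNDARY")))
    expect_equal(unname(tabn[c("Q3", "Q4", "Q1", "Q2", "BOUNDARY")]),
                 unname(tab[c("Q1", "Q2", "Q3", "Q4", "BOUNDARY")]))
  }
})

test_that("quadrant proportions plus boundary fraction sum to (N-3)/N", {
  set.seed(23)
  for (i in 1:25) {
    v <- random_window(sample(10:50, 1))
    s <- build_sodp(v)
    p <- quadrant_proportions(s)
    bnd <- sum(s$quadrants == "BOUNDARY") / s$n_source
    expect_equal(sum(p) + bnd, (s$n_source - 3) / s$n_source)
  }
})

test_that("RAS lands in the increasing band for gently increasing sequences", {
  # increments in [0.5, 1): 3*min > max keeps every derivative estimate > 0,
  # so every point sits strictly inside Q1 (Q3 after negation). The band
  # statement is about the mean point angle, i.e. the "points" denominator;
  # the literal N denominator additionally scales by (N-3)/N, which pulls
  # borderline short windows below the band edge (cf. 37*225/40 = 208.125
  # for the 40-sample linear ramp).
  set.seed(24)
  for (i in 1:20) {
    inc <- runif(sample(10:40, 1), 0.5, 1)
    up <- cumsum(inc)
    ras_up <- real_angle_sum(build_sodp(up), denominator = "points")
    expect_gt(ras_up, 0); expect_lt(ras_up, 90)
    ras_dn <- real_angle_sum(build_sodp(-up), denominator = "points")
    expect_gt(ras_dn, 180); expect_lt(ras_dn, 270)
  }
})

test_that("production angles and quadrants match the per-point oracle", {
  set.seed(25)
  for (i in 1:50) {
    v <- random_window(sample(10:50, 1))
    s <- build_sodp(v)
    oa <- mapply(oracle_angle, s$points$x, s$points$y)
    oq <- mapply(oracle_quadrant, s$points$x, s$points$y)
    expect_true(all(abs(s$angles - oa) < 1e-9, na.rm = TRUE))
    expect_equal(is.na(s$angles), is.na(oa))
    expect_equal(s$quadrants, oq)
  }
})

test_that("the SODP data-frame export carries point, angle and quadrant", {
  df <- as.data.frame(build_sodp(c(0, 1, 0, 1, 0, 1)))
  expect_named(df, c("abscissa", "ordinate", "angle_deg", "quadrant"))
  expect_equal(nrow(df), 3)
})
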