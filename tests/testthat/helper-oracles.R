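# Independent reference implementations used to cross-check the production
# code. These deliberately take the slow, per-point route.

# full-circle angle with the positive abscissa via piecewise one-argument
# arctangent (independent of the production atan2 path)
oracle_angle <- function(dx, dy) {
  if (dx == 0 && dy == 0) return(NA_real_)
  if (dx == 0) return(if (dy > 0) 90 else 270)
  if (dy == 0) return(if (dx > 0) 0 else 180)
  base <- atan(dy / dx) * 180 / pi
  if (dx > 0 && dy > 0) base
  else if (dx < 0) base + 180
  else base + 360
}

oracle_quadrant <- function(dx, dy) {
  if (dx > 0 && dy > 0) "Q1"
  else if (dx < 0 && dy > 0) "Q2"
  else if (dx < 0 && dy < 0) "Q3"
  else if (dx > 0 && dy < 0) "Q4"
  else "BOUNDARY"
}

# naive O(N^2) template-counting sample entropy (Chebyshev distance,
# self-matches excluded, N - m templates for both lengths)
naive_sample_entropy <- function(x, m, r) {
  n <- length(x)
  nm <- n - m
  a <- 0L
  b <- 0L
  for (i in 1:(nm - 1L)) {
    for (j in (i + 1L):nm) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        b <- b + 1L
        if (abs(x[i + m] - x[j + m]) <= r) a <- a + 1L
      }
    }
  }
  if (b == 0L || a == 0L) return(NA_real_)
  -log(a / b)
}

# brute-force ordinal-pattern tally (stable ties via order())
naive_permutation_entropy <- function(x, m) {
  k <- length(x) - m + 1L
  pats <- vapply(seq_len(k),
                 function(i) paste(order(x[i:(i + m - 1L)]), collapse = "-"),
                 character(1))
  p <- as.numeric(table(pats)) / k
  -sum(p * log(p)) / log(factorial(m))
}

# exact permutation p-value for a two-group Kruskal-Wallis test, enumerating
# group assignments with combn and scoring each with stats::kruskal.test
oracle_kw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  h_of <- function(idx) {
    g <- factor(replace(rep(2L, n), idx, 1L))
    unname(suppressWarnings(kruskal.test(pooled, g))$statistic)
  }
  h_obs <- h_of(seq_along(a))
  hs <- utils::combn(n, length(a), h_of)
  mean(hs >= h_obs - 1e-12)
}

# small helper: a random analysis window with occasional exact ties/zeros
random_window <- function(n) {
  v <- round(rnorm(n, 0.8, 0.05), 3)  # rounding creates genuine ties
  v
}

# window on a dyadic grid: sums, differences and power-of-two shifts/scales
# of these values are exact in IEEE arithmetic, so algebraic invariances of
# the difference plot can be asserted bit-for-bit
dyadic_window <- function(n) {
  sample.int(4097L, n, replace = TRUE) / 1024 - 2
}
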