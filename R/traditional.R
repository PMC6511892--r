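# Traditional HRV comparison metrics: heart rate, SDNN, periodogram LF/HF
# band powers, sample entropy and permutation entropy.

#' Heart rate of a window
#'
#' Mean instantaneous rate over the window: HR = mean(60 / x(n)) in
#' beats-per-minute, computed on the uniformly resampled interval values.
#' Note this is not 60 / mean(x).
#'
#' @param x A [uniform_hrv()] or numeric vector of RR values (seconds), all
#'   strictly positive.
#' @return Heart rate in bpm.
#' @examples
#' heart_rate(rep(0.8, 40)) # 75
#' @export
heart_rate <- function(x) {
  v <- .hrv_values(x)
  if (any(v <= 0)) stop("heart rate undefined for nonpositive RR values")
  mean(60 / v)
}

#' SDNN of a window
#'
#' Sample standard deviation (denominator N - 1) of the interval values,
#' reported in milliseconds.
#'
#' @param x A [uniform_hrv()] or numeric vector of RR values in seconds,
#'   length >= 2.
#' @return SDNN in ms.
#' @export
sdnn <- function(x) {
  v <- .hrv_values(x)
  if (length(v) < 2L) stop("SDNN needs at least 2 samples")
  sd(v) * 1000
}

#' One-sided windowed periodogram
#'
#' Power spectral density estimate of the demeaned signal under a Hamming
#' taper of the full window length. The normalization compensates the taper
#' energy so that a pure sinusoid of amplitude A well inside a band yields a
#' band-integrated power of A^2 / 2:
#' `P(f_k) = 2 |X_k|^2 / (fs * sum(w^2))`, with `X_k` the DFT of the tapered,
#' demeaned signal (the DC and Nyquist bins are not doubled).
#'
#' @param x A [uniform_hrv()] of length >= 8.
#' @param rate Sampling rate in Hz, taken from `x` when it is a
#'   `uniform_hrv`.
#' @return An object of class `hrv_spectrum`: list with `freqs` (Hz,
#'   ascending, up to rate/2), `power` (units^2 per Hz), `fs`, and
#'   `window_kind = "hamming"`.
#' @export
hrv_periodogram <- function(x, rate = NULL) {
  v <- .hrv_values(x)
  fs <- if (inherits(x, "uniform_hrv")) x$rate else rate
  if (is.null(fs)) stop("supply `rate` when `x` is a bare numeric vector")
  n <- length(v)
  if (n < 8L) stop("periodogram needs at least 8 samples")
  w <- as.numeric(hamming(n))
  .periodogram_vec(v, fs, w)
}

.periodogram_vec <- function(v, fs, w) {
  n <- length(v)
  xd <- (v - mean(v)) * w
  X <- fft(xd)
  nf <- n %/% 2L + 1L
  p <- 2 * Mod(X[seq_len(nf)])^2 / (fs * sum(w^2))
  p[1L] <- p[1L] / 2
  if (n %% 2L == 0L) p[nf] <- p[nf] / 2
  structure(
    list(freqs = (seq_len(nf) - 1L) * fs / n, power = p, fs = fs,
         window_kind = "hamming"),
    class = "hrv_spectrum"
  )
}

#' @export
print.hrv_spectrum <- function(x, ...) {
  cat(sprintf("<hrv_spectrum> %d bins to %.3g Hz (%s taper), df = %.4g Hz\n",
              length(x$freqs), max(x$freqs), x$window_kind,
              x$freqs[2L] - x$freqs[1L]))
  invisible(x)
}

.band_integral <- function(freqs, power, sel) {
  if (sum(sel) < 2L) return(0)
  trapz(freqs[sel], power[sel])
}

#' Spectral band powers of HRV
#'
#' Integrates the periodogram over the low-frequency (0.04-0.15 Hz) and
#' high-frequency (0.15-0.4 Hz) bands and normalizes by the 0.04-0.5 Hz band
#' power Np. Integration is trapezoidal over the bins whose centers fall in
#' the band; the shared 0.15 Hz edge is assigned to the HF band. Absolute
#' powers are in the squared input unit; normalized powers are percentages of
#' Np.
#'
#' @param spec An `hrv_spectrum` from [hrv_periodogram()]; must cover
#'   0-0.5 Hz.
#' @param lf,hf,np Band edges in Hz, `c(lo, hi)`.
#' @return List of class `band_powers`: `alf`, `ahf`, `np` (absolute),
#'   `nlf`, `nhf` (percent; `NA` with attribute `degenerate` when Np = 0).
#' @export
band_powers <- function(spec, lf = c(0.04, 0.15), hf = c(0.15, 0.4),
                        np = c(0.04, 0.5)) {
  stopifnot(inherits(spec, "hrv_spectrum"))
  f <- spec$freqs
  if (max(f) < np[2L]) {
    stop("spectrum must cover 0-", np[2L], " Hz; covers only ", max(f), " Hz")
  }
  p <- spec$power
  alf <- .band_integral(f, p, f >= lf[1L] & f < lf[2L])   # 0.15 Hz -> HF
  ahf <- .band_integral(f, p, f >= hf[1L] & f <= hf[2L])
  npw <- .band_integral(f, p, f >= np[1L] & f <= np[2L])
  if (npw <= 0) {
    nlf <- structure(NA_real_, degenerate = TRUE)
    nhf <- structure(NA_real_, degenerate = TRUE)
  } else {
    nlf <- 100 * alf / npw
    nhf <- 100 * ahf / npw
  }
  structure(list(alf = alf, ahf = ahf, np = npw, nlf = nlf, nhf = nhf),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf("<band_powers> aLF %.4g  aHF %.4g  Np %.4g | nLF %.1f%%  nHF %.1f%%\n",
              x$alf, x$ahf, x$np, x$nlf, x$nhf))
  invisible(x)
}

#' Entropy parameters
#'
#' @param m_se Embedding dimension for sample entropy (default 2).
#' @param r_factor Sample-entropy tolerance as a multiple of the window
#'   standard deviation (default 0.15).
#' @param m_pe Embedding dimension for permutation entropy (default 6;
#'   recommended range 3-7 with m! <= window length).
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(m_se = 2L, r_factor = 0.15, m_pe = 6L) {
  m_se <- as.integer(m_se); m_pe <- as.integer(m_pe)
  if (m_se < 1L) stop("`m_se` must be >= 1")
  if (r_factor <= 0) stop("`r_factor` must be > 0")
  if (m_pe < 3L || m_pe > 7L) stop("`m_pe` should be in 3..7")
  structure(list(m_se = m_se, r_factor = r_factor, m_pe = m_pe),
            class = "entropy_params")
}

#' Sample entropy
#'
#' SE = -ln(A / B), where B counts pairs of length-m templates whose
#' Chebyshev distance is within the tolerance r, and A the corresponding
#' (m+1)-template matches; self-matches are excluded and both counts run over
#' the N - m templates. The tolerance defaults to `r_factor` times the sample
#' standard deviation of the window.
#'
#' @param x A [uniform_hrv()] or numeric vector, length > m + 1.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance multiplier on the window SD (default 0.15).
#' @param r Absolute tolerance; overrides `r_factor` when given.
#' @return Sample entropy (nats). When no templates match (A or B zero) or
#'   the tolerance is zero, returns `NA` with attribute `flag` describing the
#'   degeneracy, never a silent infinity.
#' @examples
#' sample_entropy(rep(c(1, 2), 50), m = 2) # 0: perfectly regular
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.15, r = NULL) {
  v <- .hrv_values(x)
  m <- as.integer(m)
  n <- length(v)
  if (n <= m + 1L) stop("sample entropy needs more than m + 1 samples")
  if (is.null(r)) r <- r_factor * sd(v)
  if (!is.finite(r) || r <= 0) {
    return(structure(NA_real_, flag = "zero tolerance (constant window?)"))
  }
  nm <- n - m
  keep <- matrix(TRUE, nm, nm)
  idx <- seq_len(nm)
  for (k in 0:(m - 1L)) {
    xk <- v[idx + k]
    keep <- keep & abs(outer(xk, xk, "-")) <= r
  }
  b <- (sum(keep) - nm) / 2
  xk <- v[idx + m]
  a <- (sum(keep & abs(outer(xk, xk, "-")) <= r) - nm) / 2
  if (b == 0) return(structure(NA_real_, flag = "no m-template matches"))
  if (a == 0) return(structure(NA_real_, flag = "no (m+1)-template matches"))
  -log(a / b)
}

# stable ordinal ranks of every length-m window, encoded as a single integer
.ordinal_codes <- function(v, m) {
  k <- length(v) - m + 1L
  idx <- seq_len(k)
  r <- matrix(1L, k, m)
  for (i in seq_len(m)) {
    xi <- v[idx + i - 1L]
    for (j in seq_len(m)) {
      if (j == i) next
      xj <- v[idx + j - 1L]
      # ties broken by order of occurrence: earlier sample ranks lower
      r[, i] <- r[, i] + (xj < xi) + if (j < i) (xj == xi) else 0L
    }
  }
  as.vector((r - 1L) %*% m^(seq_len(m) - 1L))
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal patterns across all
#' length-m windows of the signal, normalized by log(m!) to `[0, 1]`. Ties
#' are broken by order of occurrence (stable ranking). Invariant to monotone
#' increasing transforms of the data.
#'
#' @param x A [uniform_hrv()] or numeric vector, length >= m + 1.
#' @param m Embedding dimension (default 6). A warning is issued when
#'   m! exceeds the window length, where the estimate is necessarily coarse.
#' @return Normalized permutation entropy in `[0, 1]`.
#' @examples
#' permutation_entropy(1:50, m = 3) # 0: a single ordinal pattern
#' @export
permutation_entropy <- function(x, m = 6L) {
  v <- .hrv_values(x)
  m <- as.integer(m)
  n <- length(v)
  if (n < m + 1L) stop("permutation entropy needs at least m + 1 samples")
  if (factorial(m) > n) {
    warning("m! = ", factorial(m), " exceeds window length ", n,
            "; pattern distribution is sparsely sampled")
  }
  codes <- .ordinal_codes(v, m)
  p <- tabulate(match(codes, unique(codes)))
  p <- p / sum(p)
  -sum(p * log(p)) / log(factorial(m))
}

#' All traditional metrics of one window
#'
#' Convenience wrapper computing heart rate, SDNN, the spectral band powers
#' and both entropies of a single (typically 5-min) window.
#'
#' @param x A [uniform_hrv()].
#' @param params An [entropy_params()].
#' @return A one-row data frame with columns `hr`, `sdnn`, `alf`, `ahf`,
#'   `nlf`, `nhf`, `se`, `pe`.
#' @export
traditional_metrics <- function(x, params = entropy_params()) {
  bp <- band_powers(hrv_periodogram(x))
  data.frame(
    hr = heart_rate(x),
    sdnn = sdnn(x),
    alf = bp$alf, ahf = bp$ahf,
    nlf = as.numeric(bp$nlf), nhf = as.numeric(bp$nhf),
    se = as.numeric(sample_entropy(x, m = params$m_se,
                                   r_factor = params$r_factor)),
    pe = permutation_entropy(x, m = params$m_pe)
  )
}
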