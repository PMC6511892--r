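#' Uniformly sampled HRV signal
#'
#' A tachogram on a fixed-rate grid: interval values x(n) in seconds, the
#' sampling rate, the temporal scale tau carried by the samples (1 for the
#' original signal, multiplied on coarse-graining), and the record-relative
#' time of the first sample.
#'
#' @param values Numeric vector of interval values (seconds).
#' @param rate Sampling rate in Hz (> 0).
#' @param scale Temporal scale tau of the samples (positive integer).
#' @param start_time Record-relative time of the first sample (seconds).
#' @return An object of class `uniform_hrv`.
#' @export
uniform_hrv <- function(values, rate, scale = 1L, start_time = 0) {
  values <- as.numeric(values)
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive (Hz)")
  scale <- as.integer(scale)
  if (scale < 1L) stop("`scale` must be a positive integer")
  structure(
    list(values = values, rate = rate, scale = scale,
         start_time = as.numeric(start_time)[1L]),
    class = "uniform_hrv"
  )
}

#' @export
print.uniform_hrv <- function(x, ...) {
  cat(sprintf("<uniform_hrv> %d samples @ %g Hz (scale %d), t0 = %g s\n",
              length(x$values), x$rate, x$scale, x$start_time))
  invisible(x)
}

#' @export
length.uniform_hrv <- function(x) length(x$values)

# accept either a uniform_hrv or a bare numeric vector
.hrv_values <- function(x) {
  if (inherits(x, "uniform_hrv")) x$values else as.numeric(x)
}

#' Resample an RR-interval series onto a uniform grid
#'
#' Interpolates the (beat time, RR) tachogram nodes onto a fixed-rate grid
#' starting at the first beat time. Cubic-spline interpolation is the default
#' HRV convention; linear interpolation is available for sensitivity checks.
#'
#' @param rr An [rr_series()] with at least 2 intervals.
#' @param rate Target sampling rate in Hz; 4 Hz is the conventional choice.
#' @param method `"spline"` (default) or `"linear"`.
#' @return A [uniform_hrv()] at scale 1 whose `start_time` is the first beat
#'   time.
#' @examples
#' rr <- rr_series(rep(0.8, 10))
#' resample_uniform(rr, rate = 4)
#' @export
resample_uniform <- function(rr, rate = 4, method = c("spline", "linear")) {
  stopifnot(inherits(rr, "rr_series"))
  method <- match.arg(method)
  if (length(rr$intervals) < 2L) {
    stop("resampling needs at least 2 beats; got ", length(rr$intervals))
  }
  t0 <- rr$beat_times[1L]
  t1 <- rr$beat_times[length(rr$beat_times)]
  grid <- seq(t0, t1, by = 1 / rate)
  vals <- if (method == "spline") {
    spline(rr$beat_times, rr$intervals, xout = grid, method = "fmm")$y
  } else {
    approx(rr$beat_times, rr$intervals, xout = grid)$y
  }
  uniform_hrv(vals, rate = rate, scale = 1L, start_time = t0)
}

# type-7 quartiles (linear interpolation between order statistics), fixed so
# outlier fences are bit-reproducible
.quartiles <- function(v) {
  s <- sort.int(v)
  n <- length(s)
  h1 <- (n - 1) * 0.25 + 1
  h3 <- (n - 1) * 0.75 + 1
  i1 <- floor(h1); i3 <- floor(h3)
  q1 <- s[i1] + (h1 - i1) * (s[min(i1 + 1L, n)] - s[i1])
  q3 <- s[i3] + (h3 - i3) * (s[min(i3 + 1L, n)] - s[i3])
  c(q1, q3)
}

# flag-and-replace until a fixed point: replacing an outlier tightens the
# quartiles, so a single pass can leave values outside the recomputed fences;
# iterating makes the operation idempotent (each pass either replaces at
# least one value or stops, so at most length(v) passes)
.replace_outliers_vec <- function(v, fence = "multiplicative") {
  for (pass in seq_along(v)) {
    q <- .quartiles(v)
    q1 <- q[1L]; q3 <- q[2L]
    out <- if (fence == "multiplicative") {
      v < q1 / 1.5 | v > 1.5 * q3
    } else {
      iqr <- q3 - q1
      v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr
    }
    if (!any(out)) break
    inb <- v[v >= q1 & v <= q3]
    v[out] <- if (length(inb)) median(inb) else (q1 + q3) / 2
  }
  v
}

#' Replace outlying samples within an analysis window
#'
#' Flags values outside the chosen fences and replaces them with the median of
#' the values lying inside the interquartile range `[Q1, Q3]`. The default
#' `"multiplicative"` fences flag values below `Q1 / 1.5` or above `1.5 * Q3`
#' and assume positive-valued data (RR intervals); the `"tukey"` fences
#' (`Q1 - 1.5 IQR`, `Q3 + 1.5 IQR`) are sign-symmetric and suitable for
#' arbitrary data. Quartiles use linear interpolation between order statistics
#' (type 7).
#'
#' @param x A [uniform_hrv()] or numeric vector with at least 4 samples.
#' @param fence `"multiplicative"` (default) or `"tukey"`.
#' @return Same type as `x`, same length, with outliers replaced.
#' @examples
#' replace_outliers(c(0.8, 0.8, 0.8, 5.0, 0.8))
#' @export
replace_outliers <- function(x, fence = c("multiplicative", "tukey")) {
  fence <- match.arg(fence)
  v <- .hrv_values(x)
  if (length(v) < 4L) stop("outlier replacement needs at least 4 samples")
  out <- .replace_outliers_vec(v, fence)
  if (inherits(x, "uniform_hrv")) {
    x$values <- out
    x
  } else {
    out
  }
}

.coarse_vec <- function(v, tau) {
  nb <- length(v) %/% tau
  if (tau == 1L) return(v)
  colMeans(matrix(v[seq_len(nb * tau)], nrow = tau))
}

#' Coarse-grain a uniformly sampled signal
#'
#' Block-averages the signal in nonoverlapping blocks of `tau` samples,
#' y(i) = mean of block i, for i = 1 .. floor(N / tau); trailing samples that
#' do not fill a block are dropped. The output carries scale `tau * scale(x)`
#' and rate `rate(x) / tau`.
#'
#' @param x A [uniform_hrv()] or numeric vector.
#' @param tau Positive integer scale; must not exceed the signal length.
#' @return Same type as `x`, coarse-grained.
#' @examples
#' coarse_grain(c(2, 4, 6, 8, 10, 12), 3) # 4, 10
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  v <- .hrv_values(x)
  if (tau < 1L) stop("`tau` must be >= 1")
  if (tau > length(v)) stop("`tau` (", tau, ") exceeds signal length (",
                            length(v), ")")
  y <- .coarse_vec(v, tau)
  if (inherits(x, "uniform_hrv")) {
    uniform_hrv(y, rate = x$rate / tau, scale = x$scale * tau,
                start_time = x$start_time)
  } else {
    y
  }
}

#' Sliding-window specification
#'
#' @param length_s Window duration in seconds (> 0).
#' @param step_s Increment between window starts in seconds (> 0).
#' @param scale Temporal scale tau applied inside the window (>= 1).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s, step_s = 1, scale = 1L) {
  if (length_s <= 0 || step_s <= 0) stop("window length and step must be > 0")
  structure(list(length_s = length_s, step_s = step_s,
                 scale = as.integer(scale)),
            class = "window_spec")
}

#' Cut a uniform signal into sliding windows
#'
#' Windows are half-open intervals `[start, start + length)` aligned to the
#' first grid sample, every `step_s` seconds; a trailing partial window is
#' dropped. A window of `length_s` seconds at rate `r` therefore holds exactly
#' `length_s * r` samples.
#'
#' @param x A [uniform_hrv()].
#' @param spec A [window_spec()].
#' @return A list of [uniform_hrv()] windows, each carrying its `start_time`
#'   relative to the record; empty (with a warning) if the record is shorter
#'   than one window.
#' @export
sliding_windows <- function(x, spec) {
  stopifnot(inherits(x, "uniform_hrv"), inherits(spec, "window_spec"))
  n <- length(x$values)
  len <- round(spec$length_s * x$rate)
  step <- round(spec$step_s * x$rate)
  if (len < 1L || step < 1L) stop("window shorter than one sample")
  if (len * 1 / spec$scale < 4) {
    stop("window too short for an SODP at scale ", spec$scale)
  }
  if (n < len) {
    warning("record (", n, " samples) shorter than one window (", len,
            " samples); no windows produced")
    return(list())
  }
  starts <- seq.int(1L, n - len + 1L, by = step)
  lapply(starts, function(i) {
    uniform_hrv(x$values[i:(i + len - 1L)], rate = x$rate, scale = x$scale,
                start_time = x$start_time + (i - 1L) / x$rate)
  })
}
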