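# Second-order-difference-plot construction and the four ClassA metrics.
#
# The SODP plots successive three-point forward derivative estimates of the
# HRV signal against one another: (d(n), d(n+1)) with
#   d(n) = (4 x(n+1) - 3 x(n) - x(n+2)) / 2,   n = 1 .. N-2  (1-based),
# giving N-3 points for a window of N samples. Each non-origin point gets the
# anti-clockwise angle it makes with the positive abscissa, in [0, 360)
# degrees, and a quadrant label by the strict signs of its coordinates.

# evaluated as (3(x(n+1) - x(n)) + (x(n+1) - x(n+2))) / 2, algebraically
# identical but numerically exact on constant input (the direct form
# 4x - 3x - x leaves rounding residue because 3x rounds)
.three_point_diff_vec <- function(v) {
  n <- length(v)
  mid <- v[2:(n - 1)]
  (3 * (mid - v[1:(n - 2)]) + (mid - v[3:n])) / 2
}

# anti-clockwise angle with the positive abscissa in [0, 360) degrees;
# exact axis angles for exact-zero coordinates, NA at the origin
.point_angles <- function(dx, dy) {
  a <- atan2(dy, dx) * (180 / pi)
  neg <- a < 0
  a[neg] <- a[neg] + 360
  zx <- dx == 0
  zy <- dy == 0
  a[zy & dx > 0] <- 0
  a[zx & dy > 0] <- 90
  a[zy & dx < 0] <- 180
  a[zx & dy < 0] <- 270
  a[zx & zy] <- NA_real_
  a
}

.quadrant_labels <- function(dx, dy) {
  q <- rep("BOUNDARY", length(dx))
  q[dx > 0 & dy > 0] <- "Q1"
  q[dx < 0 & dy > 0] <- "Q2"
  q[dx < 0 & dy < 0] <- "Q3"
  q[dx > 0 & dy < 0] <- "Q4"
  q
}

#' Three-point forward derivative estimate
#'
#' Computes d(n) = (4 x(n+1) - 3 x(n) - x(n+2)) / 2 for n = 1 .. N-2, a more
#' accurate first-derivative estimate than the plain first difference.
#'
#' @param x A [uniform_hrv()] or numeric vector of length >= 4.
#' @return Numeric vector of length N - 2.
#' @examples
#' three_point_forward_diff(1:10)    # all 1: exact on a linear sequence
#' @export
three_point_forward_diff <- function(x) {
  v <- .hrv_values(x)
  if (length(v) < 4L) {
    stop("need at least 4 samples for a derivative plot; got ", length(v))
  }
  .three_point_diff_vec(v)
}

#' Build the second-order-difference-plot of a window
#'
#' @param x A [uniform_hrv()] or numeric vector of length >= 4.
#' @return An object of class `sodp` with fields `points` (data frame with
#'   columns `x`, `y`), `angles` (degrees in `[0, 360)`, `NA` at the origin),
#'   `quadrants` (`"Q1"`..`"Q4"` by strict coordinate signs, `"BOUNDARY"` for
#'   any zero coordinate), and `n_source` (N, the sample count of the
#'   originating window).
#' @export
build_sodp <- function(x) {
  v <- .hrv_values(x)
  if (length(v) < 4L) {
    stop("need at least 4 samples for an SODP; got ", length(v))
  }
  d <- .three_point_diff_vec(v)
  m <- length(d)
  dx <- d[-m]
  dy <- d[-1L]
  structure(
    list(points = data.frame(x = dx, y = dy),
         angles = .point_angles(dx, dy),
         quadrants = .quadrant_labels(dx, dy),
         n_source = length(v)),
    class = "sodp"
  )
}

#' @export
print.sodp <- function(x, ...) {
  cat(sprintf("<sodp> %d points from a %d-sample window\n",
              nrow(x$points), x$n_source))
  print(table(factor(x$quadrants,
                     levels = c("Q1", "Q2", "Q3", "Q4", "BOUNDARY"))))
  invisible(x)
}

#' Export an SODP as a tidy data frame
#'
#' One row per point: abscissa, ordinate, angle (degrees) and quadrant label,
#' suitable for CSV export and scatter plotting.
#'
#' @param x An `sodp` object.
#' @param ... Unused.
#' @export
as.data.frame.sodp <- function(x, ...) {
  data.frame(abscissa = x$points$x, ordinate = x$points$y,
             angle_deg = x$angles, quadrant = x$quadrants)
}

.resolve_denominator <- function(s, denominator) {
  switch(denominator,
         n = s$n_source,
         points = nrow(s$points),
         stop("`denominator` must be \"n\" or \"points\""))
}

#' Real Angle Sum (RAS)
#'
#' The sum of the per-point anti-clockwise angles divided by N, the sample
#' count of the originating window (points at the origin contribute no
#' angle). RAS in (0, 90) degrees indicates a predominantly increasing
#' sequence, (180, 270) a predominantly decreasing one, and (90, 180) or
#' (270, 360) a balanced one. `denominator = "points"` divides by the number
#' of SODP points (N - 3) instead, for sensitivity analysis.
#'
#' @param s An `sodp` from [build_sodp()].
#' @param denominator `"n"` (default; the window sample count) or
#'   `"points"`.
#' @return RAS in degrees. If every point sits at the origin the value is 0
#'   with attribute `degenerate = TRUE`.
#' @examples
#' real_angle_sum(build_sodp(1:40))   # 37 * 45 / 40 = 41.625
#' @export
real_angle_sum <- function(s, denominator = c("n", "points")) {
  stopifnot(inherits(s, "sodp"))
  denominator <- match.arg(denominator)
  denom <- .resolve_denominator(s, denominator)
  if (all(is.na(s$angles))) {
    return(structure(0, degenerate = TRUE))
  }
  sum(s$angles, na.rm = TRUE) / denom
}

#' Quadrant occupancy proportions
#'
#' Counts of points in quadrant 1 (both derivative estimates positive:
#' cardiac deceleration), quadrants 2 and 4 together (sign change: balanced
#' HRV), and quadrant 3 (both negative: cardiac acceleration), each divided
#' by N, the originating window's sample count. Points with a zero coordinate
#' (`BOUNDARY`) count toward no quadrant.
#'
#' @inheritParams real_angle_sum
#' @return Named numeric vector `c(pq1, pq24, pq3)` with attribute
#'   `denominator`. The `pq3` component is the quadrant-3 proportion at the
#'   scale of the input signal; the pipeline computes the ClassA PQ3 from a
#'   coarse-grained signal.
#' @export
quadrant_proportions <- function(s, denominator = c("n", "points")) {
  stopifnot(inherits(s, "sodp"))
  denominator <- match.arg(denominator)
  denom <- .resolve_denominator(s, denominator)
  q <- s$quadrants
  structure(
    c(pq1 = sum(q == "Q1") / denom,
      pq24 = sum(q == "Q2" | q == "Q4") / denom,
      pq3 = sum(q == "Q3") / denom),
    denominator = denominator
  )
}

# fast path used by the pipeline: all four metrics of one window,
# without building intermediate objects
.sodp_stats_vec <- function(v, denom_points = FALSE) {
  n <- length(v)
  d <- .three_point_diff_vec(v)
  m <- length(d)
  dx <- d[-m]
  dy <- d[-1L]
  a <- .point_angles(dx, dy)
  denom <- if (denom_points) m - 1L else n
  c(ras = if (all(is.na(a))) 0 else sum(a, na.rm = TRUE) / denom,
    pq1 = sum(dx > 0 & dy > 0) / denom,
    pq24 = sum((dx < 0 & dy > 0) | (dx > 0 & dy < 0)) / denom,
    pq3 = sum(dx < 0 & dy < 0) / denom)
}

#' ClassA metrics for one analysis window pair
#'
#' Computes the four ClassA outputs: RAS, PQ1 and PQ2,4 from the
#' second-order-difference-plot of the short window at its original temporal
#' scale, and PQ3 from the quadrant-3 proportion of the SODP of the long
#' window coarse-grained by `tau`. The two window lengths reflect the
#' different speeds of the two autonomic branches: beat-to-beat (10 s)
#' dynamics for parasympathetic activity, coarse-grained 60-s dynamics for
#' sympathetic activity.
#'
#' @param x_scale1 Short window ([uniform_hrv()]) at scale 1.
#' @param x_for_pq3 Long window ([uniform_hrv()]), coarse-grained by `tau`
#'   before the quadrant-3 count.
#' @param tau Coarse-graining scale for PQ3 (default 7).
#' @param denominator `"n"` or `"points"`, see [real_angle_sum()].
#' @return An object of class `classa_result`: list with `ras`, `pq1`,
#'   `pq24`, `pq3`, `window_start`, `n_scale1`, `n_scale_tau`.
#' @export
classa_window <- function(x_scale1, x_for_pq3, tau = 7L,
                          denominator = c("n", "points")) {
  denominator <- match.arg(denominator)
  v1 <- .hrv_values(x_scale1)
  vL <- .hrv_values(x_for_pq3)
  tau <- as.integer(tau)
  if (length(v1) < 4L) stop("scale-1 window too short for an SODP")
  y <- .coarse_vec(vL, tau)
  if (length(y) < 4L) {
    stop("long window too short after coarse-graining (", length(y),
         " < 4 samples)")
  }
  s1 <- .sodp_stats_vec(v1, denominator == "points")
  sT <- .sodp_stats_vec(y, denominator == "points")
  structure(
    list(ras = unname(s1["ras"]), pq1 = unname(s1["pq1"]),
         pq24 = unname(s1["pq24"]), pq3 = unname(sT["pq3"]),
         window_start = if (inherits(x_scale1, "uniform_hrv"))
           x_scale1$start_time else NA_real_,
         n_scale1 = length(v1), n_scale_tau = length(y)),
    class = "classa_result"
  )
}

#' @export
print.classa_result <- function(x, ...) {
  cat(sprintf(
    "<classa_result> RAS %.2f deg | PQ1 %.3f  PQ2,4 %.3f  PQ3 %.3f\n",
    x$ras, x$pq1, x$pq24, x$pq3))
  cat(sprintf("  from %d samples at scale 1 and %d coarse-grained samples\n",
              x$n_scale1, x$n_scale_tau))
  invisible(x)
}
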