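# End-to-end orchestration: windowed metric series over a record, epoch
# segmentation for the stress protocol, and 30-s trajectory averaging.

#' Stress-protocol configuration
#'
#' Ordered epochs with durations, separated by fixed inter-epoch gaps. The
#' default is the standardized five-epoch protocol: 15 min each of rest,
#' mental arithmetic, meditation, step exercise and a second meditation, with
#' 1-min intervals between epochs (total 4740 s).
#'
#' @param epochs Character vector of epoch labels, or a data frame with
#'   columns `label` and `duration_s`.
#' @param duration_s Epoch duration(s) in seconds, recycled over labels when
#'   `epochs` is a character vector.
#' @param gap_s Inter-epoch interval in seconds.
#' @return A list of class `protocol_config` with an `epochs` data frame
#'   (`label`, `start_s`, `end_s`) and `gap_s`.
#' @export
protocol_config <- function(epochs = c("rest", "arithmetic", "meditation1",
                                       "exercise", "meditation2"),
                            duration_s = 900, gap_s = 60) {
  if (is.data.frame(epochs)) {
    labels <- epochs$label
    durations <- epochs$duration_s
  } else {
    labels <- epochs
    durations <- rep_len(duration_s, length(epochs))
  }
  if (any(durations <= 0)) stop("epoch durations must be > 0")
  starts <- cumsum(c(0, head(durations, -1) + gap_s))
  structure(
    list(epochs = data.frame(label = labels, start_s = starts,
                             end_s = starts + durations),
         gap_s = gap_s),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("<protocol_config> %d epochs, %g-s gaps, total %g s\n",
              nrow(x$epochs), x$gap_s, max(x$epochs$end_s)))
  print(x$epochs)
  invisible(x)
}

.metric_series <- function(metric, times, values, window_s, step_s) {
  structure(
    data.frame(time_s = times, value = values),
    metric = metric, window_s = window_s, step_s = step_s,
    class = c("metric_series", "data.frame")
  )
}

.window_starts <- function(n, rate, window_s, step_s) {
  len <- round(window_s * rate)
  step <- round(step_s * rate)
  if (n < len) return(integer(0))
  seq.int(1L, n - len + 1L, by = step)
}

#' Run the full windowed analysis over one record
#'
#' Resamples the RR series to a uniform grid and slides the three window
#' families over it: short windows (default 10 s, 1-s step) for RAS, PQ1 and
#' PQ2,4; long windows (default 60 s, 1-s step, coarse-grained at tau = 7)
#' for PQ3; and 5-min windows for the traditional metrics (HR, SDNN, aLF,
#' aHF, nLF, nHF, SE, PE). Each window is outlier-replaced before metric
#' computation (see [replace_outliers()]). Series whose window exceeds the
#' record are omitted with a warning.
#'
#' @param rr An [rr_series()].
#' @param config A [classa_config()].
#' @param metrics Which families to compute: subset of
#'   `c("classa", "traditional")`. The traditional family costs far more per
#'   window (spectra and O(N^2) entropy on 1200 samples), so long records are
#'   often run with `metrics = "classa"` or a larger `trad_step_s`.
#' @return Named list of class `metric_series_set`; each element is a data
#'   frame with columns `time_s` (window start, record-relative seconds) and
#'   `value`. Names: `ras`, `pq1`, `pq24`, `pq3`, `hr`, `sdnn`, `alf`, `ahf`,
#'   `nlf`, `nhf`, `se`, `pe`.
#' @export
run_record <- function(rr, config = classa_config(),
                       metrics = c("classa", "traditional")) {
  stopifnot(inherits(rr, "rr_series"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  x <- resample_uniform(rr, rate = config$rate, method = config$interp)
  xv <- x$values
  rate <- x$rate
  n <- length(xv)
  denom_pts <- config$denominator == "points"
  out <- list()

  if ("classa" %in% metrics) {
    # short windows: RAS, PQ1, PQ2,4 at scale 1
    len <- round(config$classa_window_s * rate)
    starts <- .window_starts(n, rate, config$classa_window_s,
                             config$classa_step_s)
    if (length(starts) == 0L) {
      warning("record shorter than one ", config$classa_window_s,
              "-s window; ClassA short-window series omitted")
    } else {
      m <- matrix(NA_real_, length(starts), 4L)
      for (k in seq_along(starts)) {
        w <- xv[starts[k]:(starts[k] + len - 1L)]
        if (config$outlier_replace) w <- .replace_outliers_vec(w, config$fence)
        m[k, ] <- .sodp_stats_vec(w, denom_pts)
      }
      times <- (starts - 1L) / rate
      out$ras <- .metric_series("ras", times, m[, 1L],
                                config$classa_window_s, config$classa_step_s)
      out$pq1 <- .metric_series("pq1", times, m[, 2L],
                                config$classa_window_s, config$classa_step_s)
      out$pq24 <- .metric_series("pq24", times, m[, 3L],
                                 config$classa_window_s, config$classa_step_s)
    }
    # long windows, coarse-grained: PQ3
    lenL <- round(config$pq3_window_s * rate)
    startsL <- .window_starts(n, rate, config$pq3_window_s, config$pq3_step_s)
    if (length(startsL) == 0L) {
      warning("record shorter than one ", config$pq3_window_s,
              "-s window; PQ3 series omitted")
    } else {
      pq3 <- numeric(length(startsL))
      for (k in seq_along(startsL)) {
        w <- xv[startsL[k]:(startsL[k] + lenL - 1L)]
        if (config$outlier_replace) w <- .replace_outliers_vec(w, config$fence)
        y <- .coarse_vec(w, config$pq3_tau)
        pq3[k] <- .sodp_stats_vec(y, denom_pts)[["pq3"]]
      }
      out$pq3 <- .metric_series("pq3", (startsL - 1L) / rate, pq3,
                                config$pq3_window_s, config$pq3_step_s)
    }
  }

  if ("traditional" %in% metrics) {
    lenT <- round(config$trad_window_s * rate)
    startsT <- .window_starts(n, rate, config$trad_window_s,
                              config$trad_step_s)
    if (length(startsT) == 0L) {
      warning("record shorter than one ", config$trad_window_s,
              "-s window; traditional series omitted")
    } else {
      ham <- as.numeric(hamming(lenT))
      mt <- matrix(NA_real_, length(startsT), 8L)
      for (k in seq_along(startsT)) {
        w <- xv[startsT[k]:(startsT[k] + lenT - 1L)]
        if (config$outlier_replace) w <- .replace_outliers_vec(w, config$fence)
        bp <- band_powers(.periodogram_vec(w, rate, ham))
        mt[k, ] <- c(mean(60 / w), sd(w) * 1000, bp$alf, bp$ahf,
                     as.numeric(bp$nlf), as.numeric(bp$nhf),
                     as.numeric(sample_entropy(w, m = config$se_m,
                                               r_factor = config$se_r_factor)),
                     permutation_entropy(w, m = config$pe_m))
      }
      timesT <- (startsT - 1L) / rate
      nms <- c("hr", "sdnn", "alf", "ahf", "nlf", "nhf", "se", "pe")
      for (j in seq_along(nms)) {
        out[[nms[j]]] <- .metric_series(nms[j], timesT, mt[, j],
                                        config$trad_window_s,
                                        config$trad_step_s)
      }
    }
  }

  class(out) <- "metric_series_set"
  attr(out, "source_id") <- rr$source_id
  out
}

#' @export
print.metric_series_set <- function(x, ...) {
  cat(sprintf("<metric_series_set> %d series%s\n", length(x),
              if (nzchar(attr(x, "source_id") %||% ""))
                paste0(" from '", attr(x, "source_id"), "'") else ""))
  for (nm in names(x)) {
    cat(sprintf("  %-5s %5d windows of %g s (step %g s)\n", nm,
                nrow(x[[nm]]), attr(x[[nm]], "window_s"),
                attr(x[[nm]], "step_s")))
  }
  invisible(x)
}

#' Flatten a metric-series set to one long data frame
#'
#' @param x A `metric_series_set` from [run_record()].
#' @param ... Unused.
#' @return Data frame with columns `metric`, `time_s`, `value`.
#' @export
as.data.frame.metric_series_set <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(nm) {
    data.frame(metric = nm, time_s = x[[nm]]$time_s, value = x[[nm]]$value)
  }))
}

#' Segment windowed series by protocol epoch
#'
#' Assigns each analysis window to the epoch containing its start time
#' (half-open epoch intervals `[start_s, end_s)`); windows starting inside an
#' inter-epoch gap are discarded. Returns the per-epoch mean of each metric,
#' the per-record summary used by the epoch statistics.
#'
#' @param series A `metric_series_set` from [run_record()], or a single
#'   `metric_series`.
#' @param protocol A [protocol_config()].
#' @return Data frame with columns `metric`, `epoch`, `value` (epoch mean)
#'   and `n_windows`. Epochs containing no windows are reported with `NA`
#'   and a warning.
#' @export
segment_by_epoch <- function(series, protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (inherits(series, "metric_series")) {
    series <- structure(list(series), class = "metric_series_set",
                        names = attr(series, "metric"))
  }
  ep <- protocol$epochs
  rows <- list()
  for (nm in names(series)) {
    s <- series[[nm]]
    for (i in seq_len(nrow(ep))) {
      inside <- s$time_s >= ep$start_s[i] & s$time_s < ep$end_s[i]
      k <- sum(inside)
      if (k == 0L) {
        warning("epoch '", ep$label[i], "' contains no '", nm, "' windows")
        val <- NA_real_
      } else {
        val <- mean(s$value[inside], na.rm = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = nm, epoch = ep$label[i], value = val, n_windows = k)
    }
  }
  do.call(rbind, rows)
}

#' Block-averaged 3-D trajectory of the quadrant proportions
#'
#' Averages the PQ1, PQ2,4 and PQ3 series over nonoverlapping 30-s blocks to
#' produce a smoothed three-dimensional trajectory (PQ2,4 against PQ3 against
#' PQ1) for plotting and state identification. The three series are first
#' restricted to their common time stamps; a trailing partial block is
#' dropped.
#'
#' @param pq1,pq24,pq3 `metric_series` from [run_record()].
#' @param block_s Block length in seconds (default 30).
#' @return Data frame of class `trajectory3d` with columns `time_s` (block
#'   centers), `pq1`, `pq24`, `pq3`; empty when the input is shorter than one
#'   block.
#' @export
average_trajectory <- function(pq1, pq24, pq3, block_s = 30) {
  common <- Reduce(intersect, list(pq1$time_s, pq24$time_s, pq3$time_s))
  if (length(common) == 0L) {
    return(structure(data.frame(time_s = numeric(0), pq1 = numeric(0),
                                pq24 = numeric(0), pq3 = numeric(0)),
                     class = c("trajectory3d", "data.frame")))
  }
  grab <- function(s) s$value[match(common, s$time_s)]
  step <- if (length(common) > 1L) min(diff(common)) else block_s
  per_block <- max(1L, round(block_s / step))
  nb <- length(common) %/% per_block
  if (nb == 0L) {
    return(structure(data.frame(time_s = numeric(0), pq1 = numeric(0),
                                pq24 = numeric(0), pq3 = numeric(0)),
                     class = c("trajectory3d", "data.frame")))
  }
  idx <- seq_len(nb * per_block)
  blk <- rep(seq_len(nb), each = per_block)
  bmean <- function(v) as.numeric(tapply(v[idx], blk, mean))
  structure(
    data.frame(
      time_s = as.numeric(tapply(common[idx], blk, mean)),
      pq1 = bmean(grab(pq1)), pq24 = bmean(grab(pq24)),
      pq3 = bmean(grab(pq3))),
    class = c("trajectory3d", "data.frame")
  )
}

#' Per-epoch block-averaged trajectories
#'
#' Applies [average_trajectory()] separately within each protocol epoch, with
#' blocks aligned to the epoch start, matching how per-epoch trajectories are
#' inspected.
#'
#' @param series A `metric_series_set` holding `pq1`, `pq24` and `pq3`.
#' @param protocol A [protocol_config()].
#' @param block_s Block length in seconds.
#' @return Data frame with columns `epoch`, `time_s`, `pq1`, `pq24`, `pq3`.
#' @export
epoch_trajectories <- function(series, protocol, block_s = 30) {
  stopifnot(all(c("pq1", "pq24", "pq3") %in% names(series)))
  ep <- protocol$epochs
  rows <- list()
  clip <- function(s, lo, hi) {
    keep <- s$time_s >= lo & s$time_s < hi
    structure(data.frame(time_s = s$time_s[keep], value = s$value[keep]),
              metric = attr(s, "metric"))
  }
  for (i in seq_len(nrow(ep))) {
    tr <- average_trajectory(clip(series$pq1, ep$start_s[i], ep$end_s[i]),
                             clip(series$pq24, ep$start_s[i], ep$end_s[i]),
                             clip(series$pq3, ep$start_s[i], ep$end_s[i]),
                             block_s = block_s)
    if (nrow(tr)) rows[[length(rows) + 1L]] <-
        cbind(epoch = ep$label[i], tr)
  }
  do.call(rbind, rows)
}
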