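# Synthetic RR-interval generation: sinusoidal LF/HF modulation around a
# baseline interval, an optional slow trend (cardiac acceleration or
# deceleration), and additive white Gaussian beat-to-beat noise, sampled at
# successive beat times. Deliberately minimal: one controllable component per
# property the analysis metrics measure.

#' Simulation specification for one RR segment
#'
#' @param duration Segment duration in seconds.
#' @param mean_rr Baseline RR interval in seconds (> 0).
#' @param lf_amp,hf_amp Amplitudes (seconds) of the low- and high-frequency
#'   sinusoidal modulations.
#' @param lf_freq,hf_freq Modulation frequencies in Hz; defaults 0.1 and 0.25
#'   sit inside the conventional LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz)
#'   bands.
#' @param trend_slope Linear drift in seconds of RR per second of record
#'   time; negative values model progressive cardiac acceleration.
#' @param noise_sd Standard deviation (seconds) of iid Gaussian beat-to-beat
#'   noise.
#' @param rr_floor Positivity floor (seconds); generated intervals are
#'   clipped here with a warning.
#' @param seed Optional integer seed for reproducible noise.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(duration = 900, mean_rr = 0.8,
                     lf_amp = 0.025, hf_amp = 0.03,
                     lf_freq = 0.1, hf_freq = 0.25,
                     trend_slope = 0, noise_sd = 0.02,
                     rr_floor = 0.3, seed = NULL) {
  if (mean_rr <= 0) stop("`mean_rr` must be > 0")
  if (duration <= 0) stop("`duration` must be > 0")
  structure(
    list(duration = duration, mean_rr = mean_rr,
         lf_amp = lf_amp, hf_amp = hf_amp,
         lf_freq = lf_freq, hf_freq = hf_freq,
         trend_slope = trend_slope, noise_sd = noise_sd,
         rr_floor = rr_floor, seed = seed),
    class = "sim_spec"
  )
}

# one segment on an absolute timeline [t_start, t_end); trend is relative to
# t_start, oscillation phases run on absolute time so concatenated segments
# stay phase-continuous
.simulate_segment <- function(spec, t_start, t_end) {
  cap <- ceiling((t_end - t_start) / spec$rr_floor) + 2L
  rr <- numeric(cap)
  bt <- numeric(cap)
  t <- t_start
  k <- 0L
  clipped <- 0L
  while (t < t_end) {
    v <- spec$mean_rr + spec$trend_slope * (t - t_start) +
      spec$lf_amp * sin(2 * pi * spec$lf_freq * t) +
      spec$hf_amp * sin(2 * pi * spec$hf_freq * t) +
      rnorm(1L, 0, spec$noise_sd)
    if (v < spec$rr_floor) {
      v <- spec$rr_floor
      clipped <- clipped + 1L
    }
    t <- t + v
    k <- k + 1L
    rr[k] <- v
    bt[k] <- t
  }
  if (clipped > 0L) {
    warning(clipped, " simulated RR value(s) clipped at the ", spec$rr_floor,
            "-s floor")
  }
  list(rr = rr[seq_len(k)], bt = bt[seq_len(k)])
}

#' Simulate an RR-interval series
#'
#' RR(t) = mean_rr + trend_slope * t + lf_amp sin(2 pi lf_freq t) +
#' hf_amp sin(2 pi hf_freq t) + noise, evaluated at successive beat times
#' (each beat advances time by the current interval). Reproducible from
#' `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @param source_id Label for the generated record.
#' @return An [rr_series()].
#' @examples
#' rr <- simulate_rr(sim_spec(duration = 60, noise_sd = 0, seed = 1))
#' @export
simulate_rr <- function(spec, source_id = "simulated") {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  seg <- .simulate_segment(spec, 0, spec$duration)
  rr_series(seg$rr, beat_times = seg$bt, source_id = source_id)
}

#' Per-epoch simulation specification for a stress protocol
#'
#' Bundles one [sim_spec()] per protocol epoch (plus one for the inter-epoch
#' gaps) into a generative description of a multi-epoch record. The default
#' parameterization emulates the canonical autonomic signatures of a
#' rest / mental-arithmetic / meditation / exercise / meditation protocol:
#' stress epochs have a shorter baseline interval (higher heart rate),
#' roughly halved HF modulation (vagal withdrawal), moderately raised LF
#' modulation (sympathetic activation) and a slow negative RR trend
#' (progressive cardiac acceleration); baselines follow typical resting
#' values (0.80 s mean RR, i.e. 75 bpm at rest; 0.65 s, i.e. ~92 bpm, during
#' exercise).
#'
#' @param protocol A [protocol_config()].
#' @param epoch_specs Named list of [sim_spec()]s, one per epoch label;
#'   `duration` fields are overridden by the protocol.
#' @param gap_spec [sim_spec()] used inside the inter-epoch gaps (default:
#'   the first epoch's spec).
#' @param seed Optional integer seed.
#' @return A list of class `protocol_sim_spec`.
#' @export
protocol_sim_spec <- function(protocol = protocol_config(),
                              epoch_specs = default_epoch_specs(),
                              gap_spec = NULL, seed = NULL) {
  labels <- protocol$epochs$label
  if (!all(labels %in% names(epoch_specs))) {
    stop("`epoch_specs` must name every protocol epoch: ",
         paste(setdiff(labels, names(epoch_specs)), collapse = ", "))
  }
  structure(
    list(protocol = protocol, epoch_specs = epoch_specs[labels],
         gap_spec = gap_spec %||% epoch_specs[[labels[1L]]], seed = seed),
    class = "protocol_sim_spec"
  )
}

#' Default per-epoch generator parameters
#'
#' @return Named list of [sim_spec()]s for the five default epochs.
#' @export
default_epoch_specs <- function() {
  list(
    rest = sim_spec(mean_rr = 0.80, lf_amp = 0.025, hf_amp = 0.030,
                    noise_sd = 0.020, trend_slope = 0),
    arithmetic = sim_spec(mean_rr = 0.74, lf_amp = 0.035, hf_amp = 0.015,
                          noise_sd = 0.025, trend_slope = -2e-5),
    meditation1 = sim_spec(mean_rr = 0.80, lf_amp = 0.025, hf_amp = 0.030,
                           noise_sd = 0.020, trend_slope = 0),
    exercise = sim_spec(mean_rr = 0.65, lf_amp = 0.030, hf_amp = 0.008,
                        noise_sd = 0.015, trend_slope = -5e-5),
    meditation2 = sim_spec(mean_rr = 0.78, lf_amp = 0.025, hf_amp = 0.030,
                           noise_sd = 0.020, trend_slope = 0)
  )
}

#' Simulate a full stress-protocol record
#'
#' Concatenates per-epoch segments and inter-epoch gap segments on one
#' continuous beat-time axis, together with the ground-truth epoch
#' annotations.
#'
#' @param pspec A [protocol_sim_spec()].
#' @param source_id Label for the generated record.
#' @return List with `rr` (an [rr_series()]) and `epochs` (data frame
#'   `label`, `start_s`, `end_s`).
#' @export
simulate_protocol <- function(pspec, source_id = "simulated-protocol") {
  stopifnot(inherits(pspec, "protocol_sim_spec"))
  if (!is.null(pspec$seed)) set.seed(pspec$seed)
  ep <- pspec$protocol$epochs
  rr <- list(); bt <- list()
  t <- 0
  for (i in seq_len(nrow(ep))) {
    if (ep$start_s[i] > t) {       # inter-epoch gap
      seg <- .simulate_segment(pspec$gap_spec, t, ep$start_s[i])
      rr[[length(rr) + 1L]] <- seg$rr
      bt[[length(bt) + 1L]] <- seg$bt
      t <- seg$bt[length(seg$bt)]
    }
    seg <- .simulate_segment(pspec$epoch_specs[[i]], t, ep$end_s[i])
    rr[[length(rr) + 1L]] <- seg$rr
    bt[[length(bt) + 1L]] <- seg$bt
    t <- seg$bt[length(seg$bt)]
  }
  list(rr = rr_series(unlist(rr), beat_times = unlist(bt),
                      source_id = source_id),
       epochs = ep)
}

#' Simulate a cohort of protocol records
#'
#' Draws `n` subjects from the same protocol specification with mild
#' between-subject variability: baseline RR shifted by N(0, 0.04 s) and
#' modulation/noise amplitudes scaled by independent log-normal factors
#' (sd 0.15 on the log scale), held constant across a subject's epochs.
#'
#' @param n Number of subjects.
#' @param pspec A [protocol_sim_spec()].
#' @param seed Optional integer seed for the whole cohort.
#' @return List of `n` results of [simulate_protocol()].
#' @export
simulate_cohort <- function(n = 10L, pspec = protocol_sim_spec(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(s) {
    drr <- rnorm(1L, 0, 0.04)
    aml <- exp(rnorm(1L, 0, 0.15))
    amh <- exp(rnorm(1L, 0, 0.15))
    amn <- exp(rnorm(1L, 0, 0.15))
    jitter <- function(sp) {
      sp$mean_rr <- max(0.4, sp$mean_rr + drr)
      sp$lf_amp <- sp$lf_amp * aml
      sp$hf_amp <- sp$hf_amp * amh
      sp$noise_sd <- sp$noise_sd * amn
      sp
    }
    ps <- pspec
    ps$epoch_specs <- lapply(pspec$epoch_specs, jitter)
    ps$gap_spec <- jitter(pspec$gap_spec)
    ps$seed <- NULL
    simulate_protocol(ps, source_id = sprintf("subject-%02d", s))
  })
}

#' Deterministic test fixtures
#'
#' Named library of uniformly sampled signals with known analytic behavior,
#' used throughout the validation suite: linear ramps (`linear_up`,
#' `linear_down`; all SODP points in Q1 resp. Q3), `constant` (degenerate:
#' every metric trivial), `alternating` (all points in Q2/Q4), single
#' sinusoids inside each spectral band (`sin_lf` at 0.1 Hz, `sin_hf` at
#' 0.3 Hz, amplitude 0.05 s, 300 s), their equal-amplitude mix
#' (`sin_lf_hf`), and seeded white `noise` (300 s).
#'
#' @param rate Sampling rate in Hz for every fixture.
#' @return Named list of [uniform_hrv()] objects.
#' @export
fixture_library <- function(rate = 4) {
  n40 <- 40L
  t300 <- seq(0, 300 - 1 / rate, by = 1 / rate)
  noise <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(20190430L)
    rnorm(length(t300), 0.8, 0.03)
  })
  list(
    linear_up = uniform_hrv(0.8 + seq_len(n40) * 0.001, rate),
    linear_down = uniform_hrv(0.9 - seq_len(n40) * 0.001, rate),
    constant = uniform_hrv(rep(0.8, n40), rate),
    alternating = uniform_hrv(rep(c(0.75, 0.85), n40 / 2L), rate),
    sin_lf = uniform_hrv(0.8 + 0.05 * sin(2 * pi * 0.1 * t300), rate),
    sin_hf = uniform_hrv(0.8 + 0.05 * sin(2 * pi * 0.3 * t300), rate),
    sin_lf_hf = uniform_hrv(0.8 + 0.05 * sin(2 * pi * 0.1 * t300) +
                              0.05 * sin(2 * pi * 0.3 * t300), rate),
    noise = uniform_hrv(noise, rate)
  )
}
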