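#' Analysis configuration
#'
#' Collects every tunable of the analysis chain in one list. Defaults follow
#' the conventional stress-protocol settings: 4 Hz cubic-spline resampling,
#' multiplicative outlier fences with in-IQR median replacement applied per
#' analysis window, 10-s/1-s ClassA windows, 60-s/1-s windows coarse-grained
#' at tau = 7 for PQ3, 5-min/1-s windows for the traditional metrics, sample
#' entropy with m = 2 and r = 0.15 SD, permutation entropy with m = 6.
#'
#' @param rate Resampling rate in Hz.
#' @param interp Interpolation for resampling: `"spline"` or `"linear"`.
#' @param fence Outlier fence rule: `"multiplicative"` (values below Q1/1.5
#'   or above 1.5 Q3) or `"tukey"`.
#' @param outlier_replace Apply per-window outlier replacement before metric
#'   computation.
#' @param denominator `"n"` (window sample count) or `"points"` (SODP point
#'   count) for RAS and the quadrant proportions.
#' @param classa_window_s,classa_step_s Short-window length/step (s) for RAS,
#'   PQ1, PQ2,4.
#' @param pq3_window_s,pq3_step_s,pq3_tau Long-window length/step (s) and
#'   coarse-graining scale for PQ3.
#' @param trad_window_s,trad_step_s Window length/step (s) for the
#'   traditional metrics.
#' @param se_m,se_r_factor,pe_m Entropy parameters, see [entropy_params()].
#' @return A list of class `classa_config`.
#' @export
classa_config <- function(rate = 4,
                          interp = c("spline", "linear"),
                          fence = c("multiplicative", "tukey"),
                          outlier_replace = TRUE,
                          denominator = c("n", "points"),
                          classa_window_s = 10, classa_step_s = 1,
                          pq3_window_s = 60, pq3_step_s = 1, pq3_tau = 7L,
                          trad_window_s = 300, trad_step_s = 1,
                          se_m = 2L, se_r_factor = 0.15, pe_m = 6L) {
  structure(
    list(rate = rate, interp = match.arg(interp), fence = match.arg(fence),
         outlier_replace = isTRUE(outlier_replace),
         denominator = match.arg(denominator),
         classa_window_s = classa_window_s, classa_step_s = classa_step_s,
         pq3_window_s = pq3_window_s, pq3_step_s = pq3_step_s,
         pq3_tau = as.integer(pq3_tau),
         trad_window_s = trad_window_s, trad_step_s = trad_step_s,
         se_m = as.integer(se_m), se_r_factor = se_r_factor,
         pe_m = as.integer(pe_m)),
    class = "classa_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' The file may hold any subset of the [classa_config()] fields, either flat
#' or grouped under the sections `preprocess`, `classa`, `traditional`;
#' unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `classa_config`.
#' @export
read_config <- function(path) {
  y <- read_yaml(path)
  flat <- list()
  for (nm in names(y)) {
    if (is.list(y[[nm]])) flat <- c(flat, y[[nm]]) else flat[nm] <- y[[nm]]
  }
  known <- names(formals(classa_config))
  unknown <- setdiff(names(flat), known)
  if (length(unknown)) {
    warning("ignoring unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(classa_config, flat[intersect(names(flat), known)])
}
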