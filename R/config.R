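#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' Defaults are the values the method is defined with: 10 s analysis
#' windows, 60 s trimming of task head and tail in training mode, a 1 s
#' trailing moving average on pressure channels, a rearfoot weight of 3 in
#' the centre-of-pressure calculation, a 0.5 Hz floor for spectral peak
#' search, and the posture thresholds 2 / 0.1 / 0.2 m s^-3 on 5 s windows.
#'
#' @param window_s Analysis window length in seconds.
#' @param trim_s Seconds removed from each end of a task in training mode.
#' @param ma_span_s Span of the trailing moving average applied to pressure
#'   channels, in seconds.
#' @param rear_weight Multiplicative weight on rearfoot sensors in the
#'   centre-of-pressure calculation.
#' @param min_freq_hz Lower frequency bound (Hz) for dominant/median
#'   frequency search, excluding the DC / postural-drift region.
#' @param cop_mode `"window_mean"` (centre of pressure of the window-mean
#'   channel values, the default) or `"per_sample"` (per-sample centre of
#'   pressure averaged over the window).
#' @param posture_window_s Posture classification window length (seconds).
#' @param avc_walk Lower AVC bound for `walking`, m s^-3.
#' @param avc_stand Upper AVC bound for `standing`, m s^-3.
#' @param avc_sit_hi Upper AVC bound for `sitting`, m s^-3 (lower bound is
#'   `avc_stand`). Values in `[avc_sit_hi, avc_walk)` are `unknown`.
#' @param min_window_fill Minimum fraction of the nominal sample count a
#'   window must contain to be emitted.
#' @param gate_mode `"full"` requires a foot window to lie entirely inside
#'   a sitting interval; `"partial"` accepts any overlap.
#' @param zscore Standardise features with training-fold statistics before
#'   discriminant fitting.
#' @param seed Integer seed recorded in run manifests.
#'
#' @return A named list of class `fs_config`.
#' @export
run_config <- function(window_s = 10, trim_s = 60, ma_span_s = 1,
                       rear_weight = 3, min_freq_hz = 0.5,
                       cop_mode = c("window_mean", "per_sample"),
                       posture_window_s = 5,
                       avc_walk = 2, avc_stand = 0.1, avc_sit_hi = 0.2,
                       min_window_fill = 0.9,
                       gate_mode = c("full", "partial"),
                       zscore = TRUE, seed = 1L) {
  cop_mode <- match.arg(cop_mode)
  gate_mode <- match.arg(gate_mode)
  stopifnot(window_s > 0, trim_s >= 0, ma_span_s > 0, rear_weight > 0,
            min_freq_hz >= 0, posture_window_s > 0,
            min_window_fill > 0, min_window_fill <= 1)
  if (!(avc_stand < avc_sit_hi && avc_sit_hi <= avc_walk))
    stop("posture thresholds must satisfy standing < sitting-upper <= walking")
  cfg <- list(window_s = window_s, trim_s = trim_s, ma_span_s = ma_span_s,
              rear_weight = rear_weight, min_freq_hz = min_freq_hz,
              cop_mode = cop_mode, posture_window_s = posture_window_s,
              avc_walk = avc_walk, avc_stand = avc_stand,
              avc_sit_hi = avc_sit_hi, min_window_fill = min_window_fill,
              gate_mode = gate_mode, zscore = zscore, seed = as.integer(seed))
  class(cfg) <- "fs_config"
  cfg
}

# standard gravity, used to convert accelerometer g units to m s^-2
GRAVITY_MS2 <- 9.80665

fs_log <- function(...) message("[footstress] ", sprintf(...))
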