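#' Acceleration vector change (AVC)
#'
#' Activity feature of a wrist-accelerometer window: the mean absolute
#' first difference of the acceleration-vector magnitude per unit time,
#' `AVC = sum_i | ||v_{i+1}|| - ||v_i|| | / T` with `v` in m s^-2 and `T`
#' the window duration in seconds, giving units of m s^-3. Channels are
#' recorded in g and converted with standard gravity. A constant vector
#' has AVC exactly 0.
#'
#' @param awin Numeric samples x 3 accelerometer matrix in g (>= 2 rows).
#' @param rate_hz Sampling rate in Hz; the window duration is
#'   `nrow(awin) / rate_hz`.
#' @return Scalar AVC in m s^-3.
#' @export
avc <- function(awin, rate_hz) {
  stopifnot(ncol(awin) == 3L, nrow(awin) >= 2L, rate_hz > 0)
  mag <- sqrt(rowSums(awin^2)) * GRAVITY_MS2
  sum(abs(diff(mag))) / (nrow(awin) / rate_hz)
}

#' Classify posture from AVC
#'
#' Threshold rule on 5 s windows: `walking` at AVC >= 2 m s^-3,
#' `standing` below 0.1 m s^-3, `sitting` in \[0.1, 0.2) m s^-3. Values in
#' the uncovered gap \[0.2, 2) m s^-3 are assigned an explicit `unknown`
#' label rather than silently widening a band; unknown windows never enter
#' the sitting mask.
#'
#' @param avc_values Numeric vector of AVC values (m s^-3).
#' @param cfg A [run_config()] carrying the thresholds.
#' @return Character vector of labels.
#' @export
classify_posture <- function(avc_values, cfg = run_config()) {
  out <- rep("unknown", length(avc_values))
  out[avc_values >= cfg$avc_walk] <- "walking"
  out[avc_values < cfg$avc_stand] <- "standing"
  out[avc_values >= cfg$avc_stand & avc_values < cfg$avc_sit_hi] <- "sitting"
  out
}

#' Posture windows of a wrist stream
#'
#' Cuts the wrist accelerometer stream into non-overlapping
#' `cfg$posture_window_s` windows anchored at the stream start and labels
#' each by its AVC ([avc()], [classify_posture()]).
#'
#' @param wrist A `wrist_accel` [sensor_stream()].
#' @param cfg A [run_config()].
#' @return Data frame with `start_s`, `end_s`, `avc`, `label`.
#' @export
posture_windows <- function(wrist, cfg = run_config()) {
  stopifnot(wrist$role == "wrist_accel")
  w <- segment_windows(wrist, cfg$posture_window_s,
                       min_fill = cfg$min_window_fill)
  if (!nrow(w)) return(data.frame(start_s = numeric(0), end_s = numeric(0),
                                  avc = numeric(0), label = character(0)))
  w$avc <- vapply(w$idx, function(i)
    avc(wrist$channels[i, , drop = FALSE], wrist$rate_hz), numeric(1))
  w$label <- classify_posture(w$avc, cfg)
  w[, c("start_s", "end_s", "avc", "label")]
}

#' Sitting mask
#'
#' Merges consecutive sitting-labelled posture windows into time
#' intervals. Foot-stream analysis windows are retained only when gated
#' by this mask (see [gate_windows()]).
#'
#' @param wrist A `wrist_accel` [sensor_stream()].
#' @param cfg A [run_config()].
#' @return Data frame of sitting intervals with `start_s`, `end_s`.
#' @export
sitting_mask <- function(wrist, cfg = run_config()) {
  pw <- posture_windows(wrist, cfg)
  sit <- pw[pw$label == "sitting", , drop = FALSE]
  if (!nrow(sit)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  new_run <- c(TRUE, sit$start_s[-1] > sit$end_s[-nrow(sit)] + 1e-9)
  run <- cumsum(new_run)
  data.frame(start_s = tapply(sit$start_s, run, min),
             end_s = tapply(sit$end_s, run, max), row.names = NULL)
}

#' Gate analysis windows by the sitting mask
#'
#' A 10 s foot window counts as sitting when it lies entirely inside one
#' sitting interval (`gate_mode = "full"`, the conservative default) or,
#' with `gate_mode = "partial"`, when it overlaps any interval.
#'
#' @param start_s,end_s Numeric vectors: the analysis windows.
#' @param mask Sitting intervals from [sitting_mask()].
#' @param gate_mode `"full"` or `"partial"`.
#' @return Logical vector: window retained.
#' @export
gate_windows <- function(start_s, end_s, mask,
                         gate_mode = c("full", "partial")) {
  gate_mode <- match.arg(gate_mode)
  vapply(seq_along(start_s), function(i) {
    if (gate_mode == "full")
      any(mask$start_s <= start_s[i] + 1e-9 & mask$end_s >= end_s[i] - 1e-9)
    else
      any(mask$start_s < end_s[i] & mask$end_s > start_s[i])
  }, logical(1))
}

#' Hourly stress ratio
#'
#' `R_S = n_stressed / n_total` over the sitting windows of one hour: the
#' fraction of sitting-posture windows the classifier labels stressed.
#' Undefined (`NA`, logged) when the hour has no sitting windows.
#'
#' @param n_stressed,n_total Window counts.
#' @return Ratio in \[0, 1\], or `NA` when `n_total` is 0.
#' @export
stress_ratio <- function(n_stressed, n_total) {
  stopifnot(length(n_stressed) == 1L, length(n_total) == 1L,
            n_stressed >= 0, n_total >= n_stressed)
  if (n_total == 0) {
    fs_log("stress ratio undefined: no sitting windows in hour")
    return(NA_real_)
  }
  n_stressed / n_total
}

#' Field-mode hourly analysis
#'
#' The full field pipeline for one participant-day: posture-segment the
#' wrist stream, gate the foot-stream 10 s windows to sitting time,
#' classify each retained window with a trained model, and summarise each
#' hour by its sitting-window count, stressed-window count and stress
#' ratio R_S, joined with the hourly self-reported stress level (SRSL)
#' when given. Hours are anchored at the foot-stream start; a trailing
#' hour not fully covered by the stream is reported but flagged
#' `partial`.
#'
#' @param insole,ankle Foot-device [sensor_stream()]s.
#' @param wrist Wrist [sensor_stream()].
#' @param model A fitted `fs_lda` model.
#' @param layout An [insole_layout()].
#' @param srsl Optional data frame `hour`, `srsl` (hour index from 0).
#' @param participant_id Id recorded in the feature rows.
#' @param cfg A [run_config()].
#' @param hour_s Hour length in seconds.
#' @return Data frame of class `fs_field_hours`: `hour`, `n_sitting`,
#'   `n_stressed`, `r_s`, `srsl`, `partial`.
#' @export
field_hours <- function(insole, ankle, wrist, model, layout,
                        srsl = NULL, participant_id = "field",
                        cfg = run_config(), hour_s = 3600) {
  t0 <- insole$timestamps[1]
  t_end <- insole$timestamps[length(insole$timestamps)] + 1 / insole$rate_hz
  meta <- session_meta(participant_id, data.frame(
    start_s = t0, end_s = t_end, task_id = "field",
    condition = "unlabelled"))
  feats <- extract_features(insole, ankle, meta, layout, cfg,
                            mode = "inference")
  mask <- sitting_mask(wrist, cfg)
  keep <- if (nrow(feats)) gate_windows(feats$window_start_s,
                                        feats$window_start_s + cfg$window_s,
                                        mask, cfg$gate_mode) else logical(0)
  feats <- feats[keep, , drop = FALSE]
  if (!nrow(feats)) fs_log("no foot windows fully inside the sitting mask")
  stressed <- if (nrow(feats)) predict(model, feats)$label == "stress"
              else logical(0)
  hour <- floor((feats$window_start_s - t0) / hour_s)
  n_hours <- max(1L, ceiling((t_end - t0) / hour_s - 1e-9))
  out <- data.frame(hour = seq_len(n_hours) - 1L)
  out$n_sitting <- vapply(out$hour, function(h) sum(hour == h), integer(1))
  out$n_stressed <- vapply(out$hour, function(h)
    sum(stressed[hour == h]), integer(1))
  out$r_s <- mapply(stress_ratio, out$n_stressed, out$n_sitting)
  out$srsl <- if (!is.null(srsl)) srsl$srsl[match(out$hour, srsl$hour)]
              else NA_real_
  out$partial <- (t0 + (out$hour + 1) * hour_s) > t_end + 1e-9
  if (any(out$partial))
    fs_log("%d trailing hour(s) only partially covered by the stream",
           sum(out$partial))
  class(out) <- c("fs_field_hours", "data.frame")
  out
}

#' Correlate the stress ratio with self-reports
#'
#' Pearson correlation between the hourly self-reported stress level and
#' the model's hourly stress ratio R_S, with a two-sided p-value. Hours
#' with an undefined R_S or missing SRSL are dropped. Fewer than 3 valid
#' hours, or zero variance in either series (e.g. a participant reporting
#' the same level all day), make the correlation undefined: `r` and `p`
#' are `NA` and the result is flagged with the reason.
#'
#' @param hours An [field_hours()] result (or any data frame with `srsl`
#'   and `r_s`).
#' @return List with `r`, `p`, `n`, `flagged`, `reason`.
#' @export
correlate_field <- function(hours) {
  ok <- stats::complete.cases(hours$srsl, hours$r_s)
  x <- hours$srsl[ok]
  y <- hours$r_s[ok]
  if (length(x) < 3)
    return(list(r = NA_real_, p = NA_real_, n = length(x), flagged = TRUE,
                reason = "fewer than 3 valid hours"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), flagged = TRUE,
                reason = "zero variance in SRSL or R_S"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       flagged = FALSE, reason = NA_character_)
}

#' Windowed electrodermal-activity summaries
#'
#' Mean and least-squares slope of the EDA signal over non-overlapping
#' windows (10 s by default), the standard validation-parity summary for
#' a 4 Hz EDA channel. Windows with fewer than 2 samples are skipped.
#'
#' @param eda An `eda` [sensor_stream()].
#' @param window_s Window length in seconds.
#' @return Data frame with `window_start_s`, `mean`, `slope` (units/s).
#' @export
eda_window_stats <- function(eda, window_s = 10) {
  stopifnot(eda$role == "eda")
  w <- segment_windows(eda, window_s, min_fill = 1e-9)
  w <- w[w$n >= 2L, , drop = FALSE]
  if (!nrow(w)) return(data.frame(window_start_s = numeric(0),
                                  mean = numeric(0), slope = numeric(0)))
  stats_ <- t(vapply(w$idx, function(i) {
    tt <- eda$timestamps[i]
    xx <- eda$channels[i, 1]
    c(mean(xx), stats::cov(tt, xx) / stats::var(tt))
  }, numeric(2)))
  data.frame(window_start_s = w$start_s, mean = stats_[, 1],
             slope = stats_[, 2])
}
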