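#' Plantar pressure features (A1-A3)
#'
#' For a window of the (moving-average-filtered) 16-channel pressure
#' stream, the forefoot pressure A1 is the window mean of the sum over
#' sensors 1-12, the rearfoot pressure A2 the window mean over sensors
#' 13-16, and the total pressure A3 the window mean over all 16 sensors,
#' so A3 = A1 + A2 identically.
#'
#' @param pwin Numeric samples x 16 matrix: the window's pressure samples.
#' @return Scalar feature value.
#' @export
forefoot_pressure <- function(pwin) {
  mean(rowSums(pwin[, FOREFOOT_IDS, drop = FALSE]))
}

#' @rdname forefoot_pressure
#' @export
rearfoot_pressure <- function(pwin) {
  mean(rowSums(pwin[, REARFOOT_IDS, drop = FALSE]))
}

#' @rdname forefoot_pressure
#' @export
total_pressure <- function(pwin) {
  # the total is the sum of the two partitions; computing it as such keeps
  # the A3 = A1 + A2 identity exact to the last bit
  forefoot_pressure(pwin) + rearfoot_pressure(pwin)
}

#' Centre of pressure (B1, B2)
#'
#' Pressure-weighted mean position of loading on the insole plane,
#' with rearfoot sensors up-weighted by `rear_weight` (default 3):
#' `XCoP = (sum_forefoot P_i x_i + w * sum_rearfoot P_i x_i) / (P_F + w P_R)`
#' and likewise for Y. By default the window-mean channel values enter the
#' formula (`mode = "window_mean"`); `mode = "per_sample"` instead computes
#' a CoP per sample and averages, which differs on time-varying loads.
#'
#' @param pwin Numeric samples x 16 pressure matrix (filtered).
#' @param layout An [insole_layout()].
#' @param rear_weight Weight applied to the four rearfoot sensors.
#' @param mode `"window_mean"` or `"per_sample"`.
#' @return Named numeric `c(B1 = XCoP, B2 = YCoP)` in layout units (mm);
#'   both `NA` when the weighted total pressure is zero (undefined CoP).
#' @export
centre_of_pressure <- function(pwin, layout, rear_weight = 3,
                               mode = c("window_mean", "per_sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "insole_layout"), ncol(pwin) == N_SENSORS)
  w <- ifelse(layout$sensor_id %in% REARFOOT_IDS, rear_weight, 1)
  cop_of <- function(p) {
    m <- w * p
    tot <- sum(m)
    if (!is.finite(tot) || tot <= 0) return(c(B1 = NA_real_, B2 = NA_real_))
    c(B1 = sum(m * layout$x) / tot, B2 = sum(m * layout$y) / tot)
  }
  if (mode == "window_mean") return(cop_of(colMeans(pwin)))
  per <- t(apply(pwin, 1L, cop_of))
  ok <- stats::complete.cases(per)
  if (!any(ok)) return(c(B1 = NA_real_, B2 = NA_real_))
  c(B1 = mean(per[ok, 1]), B2 = mean(per[ok, 2]))
}

#' Per-axis accelerometer means (C1-C3)
#'
#' Arithmetic mean of each raw ankle-accelerometer axis over the window.
#' Gravity is deliberately not subtracted: its projection onto the axes
#' encodes the leg/foot posture these features describe.
#'
#' @param awin Numeric samples x 3 matrix (ax, ay, az in g), unfiltered.
#' @return Named numeric `c(C1, C2, C3)`.
#' @export
accel_means <- function(awin) {
  m <- colMeans(awin)
  c(C1 = m[[1]], C2 = m[[2]], C3 = m[[3]])
}

#' Axis inversion
#'
#' Reflects a series about its window maximum: `2 * max(x) - x`. Applied
#' to one accelerometer axis before forming a 3D norm, it prevents
#' low-amplitude oscillations on that axis from cancelling inside the
#' norm. The map is affine with slope -1, so peak-to-peak amplitude is
#' preserved exactly.
#'
#' @param x Non-empty numeric vector.
#' @return `2 * max(x) - x`.
#' @export
invert_axis <- function(x) {
  stopifnot(length(x) > 0)
  2 * max(x) - x
}

ptp <- function(x) max(x) - min(x)

#' Inverted-axis 3D norm selection (V3D)
#'
#' Forms three candidate 3D norms from an accelerometer window, each with
#' one axis inverted ([invert_axis()]) and the other two untouched, and
#' returns the candidate with the largest peak-to-peak amplitude. Ties
#' break in axis order X, Y, Z. The winning series feeds the spectral
#' features.
#'
#' @param awin Numeric samples x 3 matrix (ax, ay, az).
#' @return Numeric vector: the selected norm series, with attribute
#'   `"axis"` naming the inverted axis (`"x"`, `"y"` or `"z"`).
#' @export
select_v3d <- function(awin) {
  stopifnot(ncol(awin) == 3L, nrow(awin) > 0L)
  cands <- lapply(1:3, function(a) {
    m <- awin
    m[, a] <- invert_axis(m[, a])
    sqrt(rowSums(m^2))
  })
  best <- which.max(vapply(cands, ptp, numeric(1)))
  structure(cands[[best]], axis = c("x", "y", "z")[best])
}

#' Spectral features of the V3D series (D1, D2)
#'
#' Removes the series mean, computes a one-sided rectangular-window
#' periodogram, and reports, over bins at or above `min_freq_hz`:
#' the dominant frequency D2 (the maximum-power bin, ties toward the
#' lower frequency) and the median frequency D1 (the smallest frequency
#' at which cumulative power reaches half the total power in the searched
#' band). A window that is constant after mean removal has no frequency
#' content; both features are 0 by convention and the result carries
#' `attr(, "flagged") = TRUE`.
#'
#' @param v3d Numeric series (at least 2 s of samples).
#' @param rate_hz Sampling rate of the series in Hz.
#' @param min_freq_hz Lower bound of the search band (default 0.5 Hz),
#'   excluding the DC / postural-drift region.
#' @return Named numeric `c(D1 = median frequency, D2 = dominant
#'   frequency)` in Hz.
#' @export
spectral_features <- function(v3d, rate_hz, min_freq_hz = 0.5) {
  n <- length(v3d)
  if (n < 2 * rate_hz) stop("spectral features need at least 2 s of samples")
  x <- v3d - mean(v3d)
  if (max(abs(x)) < 1e-12 * max(1, abs(mean(v3d)))) {
    fs_log("degenerate (constant) window: D1 = D2 = 0 by convention")
    return(structure(c(D1 = 0, D2 = 0), flagged = TRUE))
  }
  spec <- stats::fft(x)
  k <- seq_len(floor(n / 2))            # one-sided, DC excluded
  power <- Mod(spec[k + 1L])^2
  freq <- k * rate_hz / n
  band <- freq >= min_freq_hz
  if (!any(band)) {
    fs_log("no spectral bins at or above %g Hz; D1 = D2 = 0", min_freq_hz)
    return(structure(c(D1 = 0, D2 = 0), flagged = TRUE))
  }
  p <- power[band]
  f <- freq[band]
  d2 <- f[which.max(p)]                 # first maximum = lowest frequency
  d1 <- f[which(cumsum(p) >= sum(p) / 2)[1]]
  c(D1 = d1, D2 = d2)
}

#' Extract the ten-feature table from a session
#'
#' Runs the full per-window feature extraction: the pressure stream is
#' smoothed with a trailing moving average (`cfg$ma_span_s`), each task
#' segment is trimmed by `cfg$trim_s` per end in training mode (segments
#' too short to survive are excluded), and the remaining interval is cut
#' into non-overlapping `cfg$window_s` windows anchored at the (trimmed)
#' segment start. Every window present with sufficient samples in both
#' the insole and ankle streams yields one row with features A1..D2 and
#' the segment's condition as label. In training mode only `stress` /
#' `relax` segments are used; inference mode keeps all segments untrimmed.
#'
#' @param insole An `insole_pressure` [sensor_stream()].
#' @param ankle An `ankle_accel` [sensor_stream()].
#' @param meta A [session_meta()].
#' @param layout An [insole_layout()].
#' @param cfg A [run_config()].
#' @param mode `"training"` or `"inference"`.
#' @return A [feature_table()].
#' @export
extract_features <- function(insole, ankle, meta, layout,
                             cfg = run_config(),
                             mode = c("training", "inference")) {
  mode <- match.arg(mode)
  stopifnot(insole$role == "insole_pressure", ankle$role == "ankle_accel",
            inherits(meta, "session_meta"))
  pfilt <- moving_average(insole, cfg$ma_span_s)
  rows <- list()
  for (i in seq_len(nrow(meta$segments))) {
    seg <- meta$segments[i, ]
    if (mode == "training") {
      if (!seg$condition %in% c("stress", "relax")) next
      span <- trim_task(c(seg$start_s, seg$end_s), cfg$trim_s)
      if (is.null(span)) next
    } else {
      span <- c(seg$start_s, seg$end_s)
    }
    wp <- segment_windows(pfilt, cfg$window_s, origin_s = span[1],
                          end_s = span[2], min_fill = cfg$min_window_fill)
    wa <- segment_windows(ankle, cfg$window_s, origin_s = span[1],
                          end_s = span[2], min_fill = cfg$min_window_fill)
    if (!nrow(wp) || !nrow(wa)) {
      fs_log("segment %s skipped: no stream coverage in [%g, %g]",
             seg$task_id, span[1], span[2])
      next
    }
    common <- intersect(wp$start_s, wa$start_s)
    for (ws in common) {
      pwin <- pfilt$channels[wp$idx[[match(ws, wp$start_s)]], , drop = FALSE]
      awin <- ankle$channels[wa$idx[[match(ws, wa$start_s)]], , drop = FALSE]
      cop <- centre_of_pressure(pwin, layout, cfg$rear_weight, cfg$cop_mode)
      if (anyNA(cop)) {
        fs_log("window at %gs dropped: centre of pressure undefined (zero load)",
               ws)
        next
      }
      dd <- spectral_features(select_v3d(awin), ankle$rate_hz,
                              cfg$min_freq_hz)
      cm <- accel_means(awin)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = meta$participant_id, task_id = seg$task_id,
        window_start_s = ws, label = seg$condition,
        A1 = forefoot_pressure(pwin), A2 = rearfoot_pressure(pwin),
        A3 = total_pressure(pwin),
        B1 = cop[["B1"]], B2 = cop[["B2"]],
        C1 = cm[["C1"]], C2 = cm[["C2"]], C3 = cm[["C3"]],
        D1 = dd[["D1"]], D2 = dd[["D2"]])
    }
  }
  if (!length(rows)) {
    empty <- as.data.frame(stats::setNames(
      c(list(character(0), character(0), numeric(0), character(0)),
        rep(list(numeric(0)), length(FEATURE_NAMES))), FEATURE_TABLE_COLS))
    return(feature_table(empty))
  }
  feature_table(do.call(rbind, rows))
}
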