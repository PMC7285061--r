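#' Stress-signature profile for the synthetic generator
#'
#' Parameterises the four seated stress signatures the generator plants:
#' elevated forefoot loading (`forefoot_gain`, multiplicative), an
#' anterior centre-of-pressure shift (`cop_shift_mm`, the total planted
#' anterior displacement under stress, including what the forefoot gain
#' itself produces), a leg-posture change (`posture_delta_g` on the mean
#' Z-axis gravity projection), and foot tapping (a `tap_amp_g` sinusoid
#' at `tap_freq_hz` planted on the X axis in a fraction `tap_prob` of
#' stressed windows). Magnitudes are generator defaults chosen for clear
#' separability; they are synthetic choices, not measurements. Every
#' signature switches off individually (gain 1, shift 0, delta 0,
#' `tap_prob` 0), enabling single-feature ablations.
#'
#' @param forefoot_gain Forefoot pressure multiplier under stress (> 0).
#' @param cop_shift_mm Planted anterior CoP displacement under stress, mm.
#' @param posture_delta_g Shift of the mean Z-axis projection under
#'   stress, g.
#' @param tap_freq_hz Tapping frequency, Hz (must stay below Nyquist).
#' @param tap_amp_g Tapping amplitude, g.
#' @param tap_prob Fraction of stressed windows containing tapping.
#' @param noise_sd Gaussian noise SD per pressure channel, sensor units.
#' @param accel_noise_g Gaussian noise SD per accelerometer axis, g.
#' @return A list of class `stress_profile`.
#' @export
stress_profile <- function(forefoot_gain = 1.5, cop_shift_mm = 15,
                           posture_delta_g = 0.3, tap_freq_hz = 4,
                           tap_amp_g = 0.05, tap_prob = 0.7,
                           noise_sd = 2, accel_noise_g = 0.01) {
  if (!(forefoot_gain > 0)) stop("forefoot_gain must be > 0")
  if (!(tap_prob >= 0 && tap_prob <= 1)) stop("tap_prob must lie in [0, 1]")
  if (!(tap_freq_hz > 0 && tap_freq_hz < 25))
    stop("tap_freq_hz must lie in (0, 25) Hz (below the 50 Hz Nyquist)")
  if (noise_sd < 0 || accel_noise_g < 0) stop("noise SDs must be >= 0")
  p <- list(forefoot_gain = forefoot_gain, cop_shift_mm = cop_shift_mm,
            posture_delta_g = posture_delta_g, tap_freq_hz = tap_freq_hz,
            tap_amp_g = tap_amp_g, tap_prob = tap_prob,
            noise_sd = noise_sd, accel_noise_g = accel_noise_g)
  class(p) <- "stress_profile"
  p
}

#' @rdname stress_profile
#' @details `null_profile()` is the zero-effect profile (all signatures
#'   off, noise retained): stress and relax windows are then drawn from
#'   identical distributions.
#' @export
null_profile <- function(noise_sd = 2, accel_noise_g = 0.01) {
  stress_profile(forefoot_gain = 1, cop_shift_mm = 0, posture_delta_g = 0,
                 tap_prob = 0, noise_sd = noise_sd,
                 accel_noise_g = accel_noise_g)
}

#' @rdname stress_profile
#' @param ... Overrides passed to [stress_profile()].
#' @param effect Scalar in \[0, 1\] scaling every signature between the
#'   null profile (0) and the default profile (1).
#' @export
scaled_profile <- function(effect, ...) {
  stopifnot(effect >= 0, effect <= 1)
  base <- stress_profile(...)
  stress_profile(forefoot_gain = 1 + effect * (base$forefoot_gain - 1),
                 cop_shift_mm = effect * base$cop_shift_mm,
                 posture_delta_g = effect * base$posture_delta_g,
                 tap_freq_hz = base$tap_freq_hz,
                 tap_amp_g = base$tap_amp_g,
                 tap_prob = effect * base$tap_prob,
                 noise_sd = base$noise_sd,
                 accel_noise_g = base$accel_noise_g)
}

# evaluate expr under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

#' Default laboratory task plan
#'
#' Four 5-minute tasks alternating stress and relaxation, matching a
#' typical induced-stress lab session.
#'
#' @return Data frame with `duration_s`, `condition`.
#' @export
default_task_plan <- function() {
  data.frame(duration_s = rep(300, 4),
             condition = c("stress", "relax", "stress", "relax"))
}

# per-user baseline draws: resting pressure distribution and leg angle
draw_user_baseline <- function(layout, profile) {
  total <- max(200, stats::rnorm(1, 400, 40))
  fore_share <- min(0.75, max(0.45, stats::rnorm(1, 0.6, 0.04)))
  fore <- fore_share * total / 12 *
    (1 + stats::runif(12, -0.15, 0.15))
  rear <- (1 - fore_share) * total / 4 *
    (1 + stats::runif(4, -0.15, 0.15))
  accel_mean <- c(0.10, 0.20, 0.95) + stats::rnorm(3, 0, 0.05)
  list(pressure = c(fore, rear), accel_mean = accel_mean)
}

# forefoot multipliers realising the planted anterior CoP shift:
# the forefoot gain already moves the CoP forward; a linear-in-y tilt of
# the forefoot pressures (sum-preserving, clamped at 0.05) closes the
# residual to cop_shift_mm
stress_pressure_profile <- function(base, layout, profile, rear_weight = 3) {
  u <- base[FOREFOOT_IDS]
  r <- base[REARFOOT_IDS]
  s0 <- profile$forefoot_gain * u
  w_rear <- rear_weight * r
  cop_y <- function(fore) {
    (sum(fore * layout$y[FOREFOOT_IDS]) +
       sum(w_rear * layout$y[REARFOOT_IDS])) / (sum(fore) + sum(w_rear))
  }
  target <- cop_y(u) + profile$cop_shift_mm
  yF <- layout$y[FOREFOOT_IDS]
  yhat <- sum(s0 * yF) / sum(s0)
  lever <- sum(s0 * (yF - yhat)^2)
  denom <- sum(s0) + sum(w_rear)
  cc <- if (lever > 0) (target - cop_y(s0)) * denom / lever else 0
  mult <- pmax(0.05, 1 + cc * (yF - yhat))
  s <- s0 * mult
  s <- s * sum(s0) / sum(s)   # keep the forefoot sum = gain * baseline sum
  c(s, r)
}

#' Generate a labelled synthetic laboratory session
#'
#' Produces one participant's insole-pressure and ankle-accelerometer
#' streams over a task plan, the matching [session_meta()] (with
#' condition-consistent Likert ratings) and a ground-truth record.
#' Relaxation windows carry the per-user baseline: a roughly 60:40
#' forefoot:rearfoot pressure split with channel noise, and
#' gravity-dominated acceleration with slow drift. Stress windows apply
#' the profile's four signatures per 10 s window block. Fixed seeds give
#' bit-identical output (Mersenne-Twister / inversion sampling).
#'
#' @param seed Integer seed; also drives the per-user baseline draws.
#' @param profile A [stress_profile()].
#' @param task_plan Data frame `duration_s`, `condition`
#'   ([default_task_plan()] by default).
#' @param layout An [insole_layout()].
#' @param participant_id Participant identifier.
#' @param rate_hz Sampling rate of both foot streams.
#' @return List with `insole`, `ankle` ([sensor_stream()]s), `meta`
#'   ([session_meta()]) and `truth` (data frame: `task_id`,
#'   `window_start_s`, `condition`, `stressed`, `tapping`).
#' @export
generate_session <- function(seed, profile = stress_profile(),
                             task_plan = default_task_plan(),
                             layout = default_layout(),
                             participant_id = sprintf("P%02d", seed),
                             rate_hz = 50) {
  stopifnot(inherits(profile, "stress_profile"), nrow(task_plan) > 0)
  with_seed(seed, {
    base <- draw_user_baseline(layout, profile)
    stress_press <- stress_pressure_profile(base$pressure, layout, profile)
    window_s <- 10
    total_s <- sum(task_plan$duration_s)
    n <- as.integer(round(total_s * rate_hz))
    t <- (seq_len(n) - 1L) / rate_hz
    press <- matrix(rep(base$pressure, each = n), n, N_SENSORS)
    acc <- matrix(rep(base$accel_mean, each = n), n, 3L)
    # slow postural drift on each accelerometer axis
    for (a in 1:3)
      acc[, a] <- acc[, a] +
        0.01 * sin(2 * pi * 0.005 * t + stats::runif(1, 0, 2 * pi))
    starts <- cumsum(c(0, task_plan$duration_s))
    truth <- list()
    for (k in seq_len(nrow(task_plan))) {
      n_win <- floor(task_plan$duration_s[k] / window_s)
      ws <- starts[k] + (seq_len(n_win) - 1L) * window_s
      stressed <- rep(task_plan$condition[k] == "stress", n_win)
      tapping <- stressed & stats::runif(n_win) < profile$tap_prob
      for (j in seq_len(n_win)) {
        if (!stressed[j]) next
        rows <- which(t >= ws[j] - 1e-9 & t < ws[j] + window_s - 1e-9)
        press[rows, ] <- matrix(rep(stress_press, each = length(rows)),
                                length(rows), N_SENSORS)
        acc[rows, 3] <- acc[rows, 3] + profile$posture_delta_g
        if (tapping[j])
          acc[rows, 1] <- acc[rows, 1] + profile$tap_amp_g *
            sin(2 * pi * profile$tap_freq_hz * t[rows])
      }
      truth[[k]] <- data.frame(task_id = sprintf("T%d", k),
                               window_start_s = ws,
                               condition = task_plan$condition[k],
                               stressed = stressed, tapping = tapping)
    }
    press <- press + matrix(stats::rnorm(n * N_SENSORS, 0, profile$noise_sd),
                            n, N_SENSORS)
    press[press < 0] <- 0
    acc <- acc + matrix(stats::rnorm(n * 3L, 0, profile$accel_noise_g), n, 3L)
    ratings <- data.frame(
      task_id = sprintf("T%d", seq_len(nrow(task_plan))),
      stress = ifelse(task_plan$condition == "stress",
                      pmin(7L, pmax(1L, as.integer(round(
                        stats::rnorm(nrow(task_plan), 5.6, 0.7))))),
                      pmin(7L, pmax(1L, as.integer(round(
                        stats::rnorm(nrow(task_plan), 2, 0.7)))))))
    meta <- session_meta(participant_id, data.frame(
      start_s = starts[-length(starts)], end_s = starts[-1],
      task_id = ratings$task_id, condition = task_plan$condition),
      ratings)
    list(insole = sensor_stream(t, press, rate_hz, "insole_pressure"),
         ankle = sensor_stream(t, acc, rate_hz, "ankle_accel"),
         meta = meta, truth = do.call(rbind, truth))
  })
}

#' Generate a multi-user labelled feature table
#'
#' Convenience wrapper: simulates `n_users` sessions
#' ([generate_session()]), extracts features in training mode, applies
#' the ground-truth labelling rule and row-binds everything.
#'
#' @param seed Base seed; user u is generated with `seed * 1000 + u`.
#' @param n_users Number of participants.
#' @param profile A [stress_profile()].
#' @param task_plan Task plan per user.
#' @param layout An [insole_layout()].
#' @param cfg A [run_config()].
#' @return A labelled [feature_table()].
#' @export
generate_cohort_table <- function(seed, n_users = 5,
                                  profile = stress_profile(),
                                  task_plan = default_task_plan(),
                                  layout = default_layout(),
                                  cfg = run_config()) {
  tabs <- lapply(seq_len(n_users), function(u) {
    ses <- generate_session(seed * 1000 + u, profile, task_plan, layout,
                            participant_id = sprintf("P%02d", u))
    ft <- extract_features(ses$insole, ses$ankle, ses$meta, layout, cfg,
                           mode = "training")
    label_windows(ft, ses$meta)
  })
  feature_table(do.call(rbind, tabs))
}

# deterministic slot plan hitting the sitting-fraction target: cycles of
# 40 posture slots (200 s), one sitting bout then a standing/walking bout
plan_posture_slots <- function(n_slots, sitting_fraction) {
  cycle <- 40L
  n_cycles <- ceiling(n_slots / cycle)
  sit_total <- round(n_slots * sitting_fraction)
  sit_base <- floor(sit_total / n_cycles)
  extra <- sit_total - sit_base * n_cycles
  sit_per_cycle <- rep(sit_base, n_cycles) + c(rep(1L, extra),
                                               rep(0L, n_cycles - extra))
  labels <- character(0)
  for (s in sit_per_cycle) {
    other <- sample(c("standing", "walking"), 1)
    labels <- c(labels, rep("sitting", s), rep(other, cycle - s))
  }
  labels[seq_len(n_slots)]
}

#' Generate a labelled synthetic field day
#'
#' Emulates one office day of field recording: a wrist-accelerometer
#' stream (32 Hz) alternating sitting, standing and walking bouts that
#' hit a planted sitting fraction; foot streams (50 Hz) in which each
#' 10 s window lying in sitting time is stressed with probability equal
#' to that hour's planted intensity (stressed windows carry the profile's
#' signatures); an hourly self-reported stress level coupled to the
#' intensities (`SRSL = 1 + round(6 * intensity) + jitter`, clipped to
#' 1..7); and a 4 Hz EDA stream whose hourly trend follows the intensity
#' sign. Posture bouts are planted per 5 s slot so wrist windows classify
#' cleanly into the AVC bands (sitting/standing targets inside their
#' bands, walking above 2 m s^-3), scaled against the [avc()] oracle.
#'
#' @param seed Integer seed.
#' @param hourly_intensities Planted stress intensity per hour, each in
#'   \[0, 1\] (default: 8 hours ramping 0.1 to 0.8).
#' @param sitting_fraction Planted fraction of the day spent sitting.
#' @param profile A [stress_profile()].
#' @param layout An [insole_layout()].
#' @param participant_id Identifier recorded in outputs.
#' @param srsl_jitter Add the +/-1 integer jitter to the self-reports;
#'   disable to emulate a participant reporting exactly the planted level
#'   all day (e.g. a flat-rating degenerate day).
#' @return List with `insole`, `ankle`, `wrist`, `eda`
#'   ([sensor_stream()]s), `srsl` (data frame `hour`, `srsl`), and
#'   `truth` (list: `sitting_fraction`, `slots`, `windows`,
#'   `intensities`).
#' @export
generate_field_day <- function(seed,
                               hourly_intensities = seq(0.1, 0.8,
                                                        length.out = 8),
                               sitting_fraction = 0.795,
                               profile = stress_profile(),
                               layout = default_layout(),
                               participant_id = "F01",
                               srsl_jitter = TRUE) {
  stopifnot(all(hourly_intensities >= 0 & hourly_intensities <= 1),
            sitting_fraction > 0, sitting_fraction < 1)
  n_hours <- length(hourly_intensities)
  with_seed(seed, {
    slot_s <- 5
    n_slots <- n_hours * 3600L / slot_s
    slots <- plan_posture_slots(n_slots, sitting_fraction)
    wrist_rate <- 32
    spw <- slot_s * wrist_rate              # samples per posture slot
    t_rel <- (seq_len(spw) - 1L) / wrist_rate
    unit <- sin(2 * pi * 2 * t_rel)         # 2 Hz oscillation template
    unit_avc <- sum(abs(diff(unit))) * GRAVITY_MS2 / slot_s
    target <- vapply(slots, function(lb) switch(lb,
      sitting = stats::runif(1, 0.12, 0.18),
      standing = stats::runif(1, 0.02, 0.08),
      walking = stats::runif(1, 2.5, 3.5)), numeric(1))
    amp <- target / unit_avc                # g units on the magnitude axis
    wz <- 1 + as.vector(outer(unit, amp))   # samples x slots, column-major
    n_w <- n_slots * spw
    t_w <- (seq_len(n_w) - 1L) / wrist_rate
    wrist <- sensor_stream(t_w, cbind(ax = numeric(n_w), ay = numeric(n_w),
                                      az = wz), wrist_rate, "wrist_accel")

    # foot streams: baseline everywhere, stress signatures planted per
    # 10 s window fully inside a sitting bout
    rate <- 50
    base <- draw_user_baseline(layout, profile)
    stress_press <- stress_pressure_profile(base$pressure, layout, profile)
    n <- n_hours * 3600L * rate
    t <- (seq_len(n) - 1L) / rate
    press <- matrix(rep(base$pressure, each = n), n, N_SENSORS)
    acc <- matrix(rep(base$accel_mean, each = n), n, 3L)
    slot_start <- (seq_len(n_slots) - 1L) * slot_s
    sit_runs <- rle(slots == "sitting")
    run_end <- cumsum(sit_runs$lengths)
    run_start <- run_end - sit_runs$lengths + 1L
    sit_iv <- cbind(slot_start[run_start[sit_runs$values]],
                    slot_start[run_end[sit_runs$values]] + slot_s)
    win_start <- seq(0, n_hours * 3600 - 10, by = 10)
    in_sit <- vapply(win_start, function(ws)
      any(sit_iv[, 1] <= ws + 1e-9 & sit_iv[, 2] >= ws + 10 - 1e-9),
      logical(1))
    hour_of <- floor(win_start / 3600)
    stressed <- in_sit &
      stats::runif(length(win_start)) < hourly_intensities[hour_of + 1L]
    tapping <- stressed & stats::runif(length(win_start)) < profile$tap_prob
    for (j in which(stressed)) {
      rows <- (win_start[j] * rate + 1L):((win_start[j] + 10) * rate)
      press[rows, ] <- matrix(rep(stress_press, each = length(rows)),
                              length(rows), N_SENSORS)
      acc[rows, 3] <- acc[rows, 3] + profile$posture_delta_g
      if (tapping[j])
        acc[rows, 1] <- acc[rows, 1] + profile$tap_amp_g *
          sin(2 * pi * profile$tap_freq_hz * t[rows])
    }
    press <- press + matrix(stats::rnorm(n * N_SENSORS, 0, profile$noise_sd),
                            n, N_SENSORS)
    press[press < 0] <- 0
    acc <- acc + matrix(stats::rnorm(n * 3L, 0, profile$accel_noise_g), n, 3L)

    jit <- if (srsl_jitter)
      sample(c(-1L, 0L, 1L), n_hours, replace = TRUE,
             prob = c(0.15, 0.7, 0.15)) else integer(n_hours)
    srsl <- data.frame(
      hour = seq_len(n_hours) - 1L,
      srsl = pmin(7L, pmax(1L, 1L +
                             as.integer(round(6 * hourly_intensities)) + jit)))

    eda_rate <- 4
    t_e <- (seq_len(n_hours * 3600L * eda_rate) - 1L) / eda_rate
    hr_e <- pmin(floor(t_e / 3600), n_hours - 1L)
    eda_slope <- 0.0004 * (2 * hourly_intensities - 0.6)
    eda_vals <- 2 + eda_slope[hr_e + 1L] * (t_e - hr_e * 3600) +
      stats::rnorm(length(t_e), 0, 0.01)
    eda <- sensor_stream(t_e, matrix(eda_vals, ncol = 1L), eda_rate, "eda")

    list(insole = sensor_stream(t, press, rate, "insole_pressure"),
         ankle = sensor_stream(t, acc, rate, "ankle_accel"),
         wrist = wrist, eda = eda, srsl = srsl,
         truth = list(sitting_fraction = mean(slots == "sitting"),
                      slots = data.frame(start_s = slot_start, label = slots),
                      windows = data.frame(window_start_s = win_start,
                                           sitting = in_sit,
                                           stressed = stressed,
                                           tapping = tapping),
                      intensities = hourly_intensities))
  })
}
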