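# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# gap-free stream of `secs` seconds at `rate` Hz with the given channels
make_stream <- function(channels, rate, role, secs = NULL) {
  n <- if (is.null(secs)) nrow(channels) else as.integer(round(secs * rate))
  if (is.null(dim(channels)))
    channels <- matrix(channels, n, length(channels), byrow = TRUE)
  sensor_stream((seq_len(n) - 1L) / rate, channels, rate, role)
}

# constant-pressure insole stream: one value per sensor
pressure_stream <- function(per_sensor, secs = 10, rate = 50) {
  make_stream(matrix(rep(per_sensor, each = secs * rate), ncol = 16),
              rate, "insole_pressure")
}

# accel stream around a constant mean vector
accel_stream <- function(mean_vec = c(0, 0, 1), secs = 10, rate = 50,
                         role = "ankle_accel") {
  make_stream(matrix(rep(mean_vec, each = secs * rate), ncol = 3),
              rate, role)
}

# a random non-negative pressure window (samples x 16)
random_pressure_window <- function(n = 50) {
  matrix(stats::runif(n * 16, 0, 100), n, 16)
}

# meta for a single task covering [0, dur)
single_task_meta <- function(dur, condition = "stress", rating = 6,
                             id = "P01") {
  session_meta(id,
               data.frame(start_s = 0, end_s = dur, task_id = "T1",
                          condition = condition),
               data.frame(task_id = "T1", stress = rating))
}

# is (px, py) inside (or on) the convex hull of layout points?
in_hull <- function(px, py, x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  m <- length(h)
  s <- vapply(seq_len(m), function(i) {
    j <- if (i == m) 1L else i + 1L
    (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
  }, numeric(1))
  all(s <= 1e-9) || all(s >= -1e-9)
}

# task plan giving `n_win` training windows per task after 60 s trimming
plan_with_windows <- function(n_win, n_tasks = 4) {
  data.frame(duration_s = rep(n_win * 10 + 120, n_tasks),
             condition = rep(c("stress", "relax"), length.out = n_tasks))
}

# write a small cohort of session artifacts to per-user directories
cohort_dirs <- function(root, seeds, plan) {
  vapply(seq_along(seeds), function(i) {
    d <- file.path(root, sprintf("u%d", i))
    ses <- generate_session(seeds[i], task_plan = plan,
                            participant_id = sprintf("P%02d", i))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_stream(ses$insole, file.path(d, "insole.csv"))
    write_stream(ses$ankle, file.path(d, "ankle.csv"))
    write_session_meta(ses$meta, file.path(d, "meta.yaml"))
    d
  }, character(1))
}
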