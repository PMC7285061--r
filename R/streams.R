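#' Uniformly sampled multichannel sensor stream
#'
#' A `sensor_stream` couples a strictly increasing timestamp vector
#' (seconds) with a samples x channels matrix and a role that fixes the
#' channel semantics:
#'
#' * `insole_pressure` - 16 non-negative pressure channels `p1..p16`
#'   (raw sensor units), nominally 50 Hz;
#' * `ankle_accel` - 3 channels `ax, ay, az` in g, nominally 50 Hz;
#' * `wrist_accel` - 3 channels `ax, ay, az` in g, nominally 32 Hz;
#' * `eda` - 1 channel `eda` (microsiemens), nominally 4 Hz.
#'
#' Timestamps are authoritative; `rate_hz` is the nominal rate used for
#' window bookkeeping. A stream whose median inter-sample gap deviates
#' from `1/rate_hz` by more than 10% is rejected.
#'
#' @param timestamps Numeric vector, seconds, strictly increasing.
#' @param channels Numeric matrix, `length(timestamps)` rows.
#' @param rate_hz Nominal sampling rate in Hz.
#' @param role One of `"insole_pressure"`, `"ankle_accel"`,
#'   `"wrist_accel"`, `"eda"`.
#'
#' @return A list of class `sensor_stream` with elements `timestamps`,
#'   `channels`, `rate_hz`, `role`.
#' @export
sensor_stream <- function(timestamps, channels, rate_hz, role) {
  role <- match.arg(role, names(ROLE_CHANNELS))
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  s <- list(timestamps = as.numeric(timestamps), channels = channels,
            rate_hz = as.numeric(rate_hz), role = role)
  class(s) <- "sensor_stream"
  validate_stream(s)
}

ROLE_CHANNELS <- list(
  insole_pressure = paste0("p", 1:16),
  ankle_accel = c("ax", "ay", "az"),
  wrist_accel = c("ax", "ay", "az"),
  eda = "eda"
)

validate_stream <- function(s) {
  want <- ROLE_CHANNELS[[s$role]]
  n <- length(s$timestamps)
  if (n == 0L) stop("empty stream (role ", s$role, ")")
  if (nrow(s$channels) != n)
    stop("channel matrix has ", nrow(s$channels), " rows for ",
         n, " timestamps")
  if (ncol(s$channels) != length(want))
    stop("role '", s$role, "' requires ", length(want),
         " channels, got ", ncol(s$channels))
  colnames(s$channels) <- want
  if (anyNA(s$timestamps) || anyNA(s$channels))
    stop("stream contains missing values")
  if (n > 1L && any(diff(s$timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (s$role == "insole_pressure" && any(s$channels < 0))
    stop("pressure values must be non-negative")
  if (n > 1L) {
    gap <- stats::median(diff(s$timestamps))
    nominal <- 1 / s$rate_hz
    if (abs(gap - nominal) > 0.1 * nominal)
      stop(sprintf(paste0("median inter-sample gap %.6gs deviates more than ",
                          "10%% from nominal %.6gs (rate %g Hz)"),
                   gap, nominal, s$rate_hz))
  }
  s
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream %s: %d samples x %d channels, %g Hz, %.1f s>\n",
              x$role, length(x$timestamps), ncol(x$channels), x$rate_hz,
              diff(range(x$timestamps))))
  invisible(x)
}

stream_duration <- function(s) {
  s$timestamps[length(s$timestamps)] - s$timestamps[1]
}

#' Read a sensor stream from CSV
#'
#' Expects a header `t,<c1>,...,<cn>` whose channel count matches the
#' role (`p1..p16` for pressure, `ax,ay,az` for accelerometers, `eda` for
#' electrodermal activity) and numeric seconds in `t`.
#'
#' @param path CSV file path.
#' @param role Stream role, see [sensor_stream()].
#' @param rate_hz Nominal sampling rate in Hz.
#' @return A validated [sensor_stream()].
#' @export
read_stream <- function(path, role, rate_hz) {
  role <- match.arg(role, names(ROLE_CHANNELS))
  if (!file.exists(path)) stop("stream file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = ","),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (names(dt)[1] != "t")
    stop("stream CSV '", path, "' must start with a 't' column")
  want <- ROLE_CHANNELS[[role]]
  if (ncol(dt) - 1L != length(want))
    stop("stream CSV '", path, "' has ", ncol(dt) - 1L,
         " channel columns; role '", role, "' requires ", length(want))
  nonnum <- names(dt)[!vapply(dt, is.numeric, logical(1))]
  if (length(nonnum)) {
    # locate the first offending value for the diagnostic
    col <- nonnum[1]
    bad <- suppressWarnings(which(is.na(as.numeric(dt[[col]]))))[1]
    stop("non-numeric value in column '", col, "' of '", path,
         "' (data line ", ifelse(is.na(bad), NA, bad), ")")
  }
  sensor_stream(dt[[1]], as.matrix(dt[, -1]), rate_hz = rate_hz, role = role)
}

#' Write a sensor stream to CSV
#'
#' Values round-trip through [read_stream()] losslessly to at least 12
#' significant digits.
#'
#' @param stream A [sensor_stream()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stream <- validate_stream(stream)
  dt <- data.table::data.table(t = stream$timestamps)
  dt <- cbind(dt, data.table::as.data.table(stream$channels))
  data.table::fwrite(dt, path)
  invisible(path)
}
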