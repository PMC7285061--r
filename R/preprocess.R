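#' Trailing moving-average filter
#'
#' Smooths every channel with a trailing (causal) moving average of
#' `span_s` seconds: each output sample is the mean of the input samples
#' in the preceding span, with a shorter prefix at the stream start.
#' Sample count and timestamps are unchanged. The filter is used on the
#' pressure channels before any pressure feature is summed; accelerometer
#' features are computed on raw samples.
#'
#' @param stream A [sensor_stream()].
#' @param span_s Filter span in seconds (default 1 s).
#' @return A filtered [sensor_stream()].
#' @export
moving_average <- function(stream, span_s = 1.0) {
  stopifnot(inherits(stream, "sensor_stream"), span_s > 0)
  k <- max(1L, as.integer(round(span_s * stream$rate_hz)))
  x <- stream$channels
  n <- nrow(x)
  if (k > 1L && n > 1L) {
    cs <- apply(x, 2L, cumsum)
    if (n == 1L) cs <- matrix(cs, nrow = 1L)
    out <- cs
    if (n > k) {
      idx <- (k + 1L):n
      out[idx, ] <- cs[idx, , drop = FALSE] - cs[idx - k, , drop = FALSE]
    }
    denom <- pmin(seq_len(n), k)
    stream$channels <- out / denom
    colnames(stream$channels) <- colnames(x)
  }
  stream
}

#' Segment a stream into non-overlapping windows
#'
#' Windows of `length_s` seconds are anchored at `origin_s` (the stream
#' start by default) and tiled consecutively; the trailing partial window
#' is dropped. A window is emitted only if it contains at least
#' `min_fill` of its nominal sample count (`length_s * rate_hz`), so gaps
#' larger than that suppress the affected windows rather than producing
#' sparse ones.
#'
#' @param stream A [sensor_stream()].
#' @param length_s Window length in seconds (default 10 s).
#' @param origin_s Anchor time; windows start at
#'   `origin_s, origin_s + length_s, ...`.
#' @param end_s Do not start windows at or beyond this time (defaults to
#'   just past the last sample).
#' @param min_fill Minimum fraction of the nominal sample count.
#' @return A data frame with columns `start_s`, `end_s`, `n` and a list
#'   column `idx` of sample indices into the stream; zero rows when the
#'   stream is shorter than one window.
#' @export
segment_windows <- function(stream, length_s = 10.0,
                            origin_s = stream$timestamps[1],
                            end_s = NULL, min_fill = 0.9) {
  stopifnot(inherits(stream, "sensor_stream"), length_s > 0)
  t <- stream$timestamps
  dt_nom <- 1 / stream$rate_hz
  # each sample notionally covers 1/rate, so a stream of n gap-free samples
  # spans n/rate seconds even though last - first = (n-1)/rate
  if (is.null(end_s)) end_s <- t[length(t)] + dt_nom
  n_win <- floor((end_s - origin_s) / length_s + 1e-9)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n = integer(0))
  empty$idx <- list()
  if (n_win < 1) return(empty)
  nominal <- length_s * stream$rate_hz
  starts <- origin_s + (seq_len(n_win) - 1L) * length_s
  lo <- findInterval(starts - 1e-9, t) + 1L
  hi <- findInterval(starts + length_s - 1e-9, t)
  keep <- (hi - lo + 1L) >= min_fill * nominal
  if (!any(keep)) return(empty)
  out <- data.frame(start_s = starts[keep], end_s = starts[keep] + length_s,
                    n = (hi - lo + 1L)[keep])
  out$idx <- Map(seq.int, lo[keep], hi[keep])
  out
}

#' Trim task accustomisation and exhaustion periods
#'
#' Training-mode segments lose their first and last `trim_s` seconds to
#' exclude task accustomisation at the start and exhaustion at the end.
#' Segments no longer than `2 * trim_s` have nothing left and are
#' rejected.
#'
#' @param segment Numeric length-2 vector `c(start_s, end_s)`.
#' @param trim_s Seconds trimmed from each end (default 60 s).
#' @return `c(start_s + trim_s, end_s - trim_s)`, or `NULL` (with a
#'   logged reason) when the segment is too short to survive trimming.
#' @export
trim_task <- function(segment, trim_s = 60) {
  stopifnot(length(segment) == 2L, trim_s >= 0)
  if (segment[2] - segment[1] <= 2 * trim_s) {
    fs_log("segment [%g, %g] excluded: %.3gs duration leaves nothing after trimming %gs per end",
           segment[1], segment[2], segment[2] - segment[1], trim_s)
    return(NULL)
  }
  c(segment[1] + trim_s, segment[2] - trim_s)
}
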