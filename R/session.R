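#' Session metadata
#'
#' Describes one recording session: the participant, the ordered task
#' segments with their experimental condition, and the post-task
#' questionnaire ratings (perceived stress on a 1-7 Likert scale, plus
#' optional energy, pleasantness and task-load entries).
#'
#' @param participant_id Character scalar.
#' @param segments Data frame with columns `start_s`, `end_s`, `task_id`,
#'   `condition` (`"stress"`, `"relax"` or `"unlabelled"`); segments must
#'   be non-overlapping with `end_s > start_s`.
#' @param ratings Data frame with columns `task_id`, `stress` (integer
#'   1-7) and optionally `energy`, `pleasantness`, `tlx`. May be omitted
#'   for inference-only sessions, but every labelled segment used in
#'   training needs a stress rating.
#'
#' @return A list of class `session_meta`.
#' @export
session_meta <- function(participant_id, segments, ratings = NULL) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  segments <- as.data.frame(segments)
  need <- c("start_s", "end_s", "task_id", "condition")
  if (!all(need %in% names(segments)))
    stop("segments must have columns ", paste(need, collapse = ", "))
  segments <- segments[order(segments$start_s), , drop = FALSE]
  rownames(segments) <- NULL
  if (any(segments$end_s <= segments$start_s))
    stop("every segment needs end_s > start_s")
  if (nrow(segments) > 1L &&
      any(segments$start_s[-1] < segments$end_s[-nrow(segments)]))
    stop("segments must be non-overlapping")
  ok <- segments$condition %in% c("stress", "relax", "unlabelled")
  if (!all(ok))
    stop("unknown condition(s): ",
         paste(unique(segments$condition[!ok]), collapse = ", "))
  if (!is.null(ratings)) {
    ratings <- as.data.frame(ratings)
    if (!all(c("task_id", "stress") %in% names(ratings)))
      stop("ratings must have columns task_id and stress")
    bad <- !(ratings$stress %in% 1:7)
    if (any(bad))
      stop("stress ratings must be integers on the 1..7 Likert scale")
  }
  m <- list(participant_id = participant_id, segments = segments,
            ratings = ratings)
  class(m) <- "session_meta"
  m
}

#' Read / write session metadata (YAML)
#'
#' @param path YAML file path.
#' @return [session_meta()] for the reader; `path` invisibly for the writer.
#' @export
read_session_meta <- function(path) {
  if (!file.exists(path)) stop("session meta file not found: ", path)
  doc <- yaml::read_yaml(path)
  segs <- do.call(rbind, lapply(doc$segments, function(s)
    data.frame(start_s = as.numeric(s$start_s), end_s = as.numeric(s$end_s),
               task_id = as.character(s$task_id),
               condition = as.character(s$condition))))
  ratings <- NULL
  if (length(doc$ratings)) {
    ratings <- do.call(rbind, lapply(doc$ratings, function(r) {
      row <- data.frame(task_id = as.character(r$task_id),
                        stress = as.integer(r$stress))
      for (extra in c("energy", "pleasantness", "tlx"))
        if (!is.null(r[[extra]])) row[[extra]] <- as.numeric(r[[extra]])
      row
    }))
  }
  session_meta(doc$participant_id, segs, ratings)
}

#' @rdname read_session_meta
#' @param meta A [session_meta()].
#' @export
write_session_meta <- function(meta, path) {
  stopifnot(inherits(meta, "session_meta"))
  segs <- lapply(seq_len(nrow(meta$segments)), function(i)
    as.list(meta$segments[i, , drop = FALSE]))
  out <- list(participant_id = meta$participant_id,
              segments = lapply(segs, function(s) lapply(s, unname)))
  if (!is.null(meta$ratings))
    out$ratings <- lapply(seq_len(nrow(meta$ratings)), function(i)
      lapply(as.list(meta$ratings[i, , drop = FALSE]), unname))
  yaml::write_yaml(out, path)
  invisible(path)
}

FEATURE_NAMES <- c("A1", "A2", "A3", "B1", "B2",
                   "C1", "C2", "C3", "D1", "D2")
FEATURE_TABLE_COLS <- c("participant_id", "task_id", "window_start_s",
                        "label", FEATURE_NAMES)

#' Feature tables
#'
#' One row per emitted 10 s window with the ten features: A1 forefoot
#' pressure, A2 rearfoot pressure, A3 total pressure (window means of
#' channel sums), B1/B2 the centre-of-pressure x/y coordinates (mm), C1-C3
#' the per-axis ankle accelerometer means (g), D1 the median and D2 the
#' dominant frequency (Hz) of the axis-inverted 3D acceleration norm.
#' Column order is fixed: participant_id, task_id, window_start_s, label,
#' A1..D2.
#'
#' @param df Data frame holding the fixed columns.
#' @return `df` with class `feature_table`, columns ordered canonically.
#' @export
feature_table <- function(df) {
  df <- as.data.frame(df)
  miss <- setdiff(FEATURE_TABLE_COLS, names(df))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, FEATURE_TABLE_COLS, drop = FALSE]
  if (nrow(df) && anyNA(df[, FEATURE_NAMES]))
    stop("feature table must not contain missing feature values")
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Read / write a feature table (CSV)
#'
#' Round-trips losslessly to at least 12 significant digits; an empty
#' table writes a header-only file and reads back empty.
#'
#' @param path CSV file path.
#' @return [feature_table()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = c(
                            "participant_id", "task_id", "label")))
  feature_table(as.data.frame(dt))
}

#' @rdname read_feature_table
#' @param table A [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(table)
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}
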