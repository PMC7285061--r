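#' Run manifest
#'
#' Every pipeline command writes a `manifest.json` next to its artifacts
#' recording the configuration, the seed, MD5 digests of the input files
#' and the package/R versions, so a run is reproducible and re-runs with
#' identical manifests are idempotent.
#'
#' @param out_dir Output directory.
#' @param cfg A [run_config()].
#' @param inputs Character vector of input file paths (digested).
#' @param extra Named list merged into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, cfg, inputs = character(0),
                           extra = list()) {
  man <- c(list(
    config = unclass(cfg),
    seed = cfg$seed,
    inputs = as.list(tools::md5sum(inputs)),
    package_version = as.character(utils::packageVersion("footstress")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")),
    extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline commands
#'
#' Thin, path-oriented wrappers that wire the modules into reproducible
#' commands; the `footstress` command-line script dispatches to these.
#' All commands leave their inputs untouched and write artifacts plus a
#' [write_manifest()] to `out_dir`.
#'
#' `run_synth()` generates a synthetic session (`mode = "session"`:
#' `insole.csv`, `ankle.csv`, `meta.yaml`, `truth.json`) or field day
#' (`mode = "field"`: adds `wrist.csv`, `eda.csv`, `srsl.csv`).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param mode `"session"` or `"field"`.
#' @param profile A [stress_profile()].
#' @param cfg A [run_config()].
#' @return `out_dir`, invisibly.
#' @export
run_synth <- function(out_dir, seed, mode = c("session", "field"),
                      profile = stress_profile(), cfg = run_config()) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$seed <- as.integer(seed)
  if (mode == "session") {
    ses <- generate_session(seed, profile)
    write_stream(ses$insole, file.path(out_dir, "insole.csv"))
    write_stream(ses$ankle, file.path(out_dir, "ankle.csv"))
    write_session_meta(ses$meta, file.path(out_dir, "meta.yaml"))
    jsonlite::write_json(ses$truth, file.path(out_dir, "truth.json"),
                         digits = NA, dataframe = "columns")
  } else {
    day <- generate_field_day(seed, profile = profile)
    write_stream(day$insole, file.path(out_dir, "insole.csv"))
    write_stream(day$ankle, file.path(out_dir, "ankle.csv"))
    write_stream(day$wrist, file.path(out_dir, "wrist.csv"))
    write_stream(day$eda, file.path(out_dir, "eda.csv"))
    data.table::fwrite(day$srsl, file.path(out_dir, "srsl.csv"))
    jsonlite::write_json(day$truth, file.path(out_dir, "truth.json"),
                         digits = NA, dataframe = "columns")
  }
  write_manifest(out_dir, cfg, extra = list(command = "synth", mode = mode))
  invisible(out_dir)
}

#' @rdname run_synth
#' @details `run_extract()` reads the two foot streams and the session
#'   metadata and writes `features.csv`.
#' @param insole_csv,ankle_csv,meta_yaml Input artifact paths.
#' @param layout_yaml Optional layout file (bundled default otherwise).
#' @param extract_mode `"training"` (trimmed, labelled segments only) or
#'   `"inference"`.
#' @export
run_extract <- function(out_dir, insole_csv, ankle_csv, meta_yaml,
                        layout_yaml = NULL, cfg = run_config(),
                        extract_mode = c("training", "inference")) {
  extract_mode <- match.arg(extract_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- if (is.null(layout_yaml)) default_layout()
            else read_layout(layout_yaml)
  insole <- read_stream(insole_csv, "insole_pressure", 50)
  ankle <- read_stream(ankle_csv, "ankle_accel", 50)
  meta <- read_session_meta(meta_yaml)
  ft <- extract_features(insole, ankle, meta, layout, cfg, extract_mode)
  write_feature_table(ft, file.path(out_dir, "features.csv"))
  write_manifest(out_dir, cfg,
                 inputs = c(insole_csv, ankle_csv, meta_yaml,
                            if (!is.null(layout_yaml)) layout_yaml),
                 extra = list(command = "extract", mode = extract_mode,
                              n_windows = nrow(ft)))
  invisible(out_dir)
}

#' @rdname run_synth
#' @details `run_train()` concatenates one or more feature tables,
#'   applies the ground-truth labelling rule using the matching session
#'   metadata, fits the discriminant on `features` and writes
#'   `model.json`.
#' @param table_csvs Character vector of feature-table CSVs.
#' @param meta_yamls Character vector of session-metadata YAMLs.
#' @param features Feature subset, e.g. `c("A1","B2","C3","D1")`.
#' @export
run_train <- function(out_dir, table_csvs, meta_yamls, features,
                      cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- feature_table(do.call(rbind, lapply(table_csvs, read_feature_table)))
  metas <- lapply(meta_yamls, read_session_meta)
  tab <- label_windows(tab, metas)
  model <- fit_lda(tab, features, zscore = cfg$zscore)
  write_model(model, file.path(out_dir, "model.json"))
  write_manifest(out_dir, cfg, inputs = c(table_csvs, meta_yamls),
                 extra = list(command = "train",
                              features = paste(features, collapse = "+"),
                              n_rows = nrow(tab)))
  invisible(out_dir)
}

#' @rdname run_synth
#' @details `run_evaluate()` performs leave-one-user-out evaluation of
#'   `features` on the labelled concatenated tables and writes
#'   `report.json` plus `accuracy_curve.csv`.
#' @export
run_evaluate <- function(out_dir, table_csvs, meta_yamls, features,
                         cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- feature_table(do.call(rbind, lapply(table_csvs, read_feature_table)))
  metas <- lapply(meta_yamls, read_session_meta)
  tab <- label_windows(tab, metas)
  rep <- leave_one_user_out(tab, features, zscore = cfg$zscore)
  jsonlite::write_json(
    list(feature_subset = rep$feature_subset,
         mean_accuracy = rep$mean_accuracy, sd_accuracy = rep$sd_accuracy,
         p_separation = rep$p_separation, per_user = rep$per_user),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", pretty = TRUE)
  data.table::fwrite(rep$curve, file.path(out_dir, "accuracy_curve.csv"))
  write_manifest(out_dir, cfg, inputs = c(table_csvs, meta_yamls),
                 extra = list(command = "evaluate",
                              features = paste(features, collapse = "+")))
  invisible(out_dir)
}

#' @rdname run_synth
#' @details `run_field()` runs the field pipeline: posture segmentation
#'   of the wrist stream, sitting-gated classification of the foot
#'   streams with a trained model, hourly stress ratios joined with the
#'   SRSL log, writing `hours.csv` and `field_summary.json`.
#' @param wrist_csv Wrist stream CSV (32 Hz).
#' @param model_json Trained model file.
#' @param srsl_csv Hourly self-report CSV with columns `hour`, `srsl`.
#' @export
run_field <- function(out_dir, insole_csv, ankle_csv, wrist_csv, model_json,
                      srsl_csv = NULL, layout_yaml = NULL,
                      cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- if (is.null(layout_yaml)) default_layout()
            else read_layout(layout_yaml)
  insole <- read_stream(insole_csv, "insole_pressure", 50)
  ankle <- read_stream(ankle_csv, "ankle_accel", 50)
  wrist <- read_stream(wrist_csv, "wrist_accel", 32)
  model <- read_model(model_json)
  srsl <- if (!is.null(srsl_csv))
    as.data.frame(data.table::fread(srsl_csv)) else NULL
  hours <- field_hours(insole, ankle, wrist, model, layout, srsl = srsl,
                       cfg = cfg)
  data.table::fwrite(as.data.frame(hours), file.path(out_dir, "hours.csv"))
  corr <- correlate_field(hours)
  jsonlite::write_json(corr, file.path(out_dir, "field_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, cfg,
                 inputs = c(insole_csv, ankle_csv, wrist_csv, model_json,
                            srsl_csv),
                 extra = list(command = "field"))
  invisible(out_dir)
}
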