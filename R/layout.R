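#' Insole sensor layout
#'
#' An `insole_layout` describes where each of the 16 force-sensitive
#' resistors sits on the insole plane and which anatomical region it
#' belongs to. Sensors 1-12 are the forefoot partition, sensors 13-16 the
#' rearfoot (heel) partition; the pressure and centre-of-pressure features
#' are defined on exactly this split. Coordinates are millimetres:
#' x medio-lateral, y anterior-posterior (larger y = more anterior).
#'
#' @param sensor_id Integer vector 1..16 (any order, each exactly once).
#' @param x,y Numeric planar coordinates in mm, all finite.
#' @param region Character, `"forefoot"` for ids 1-12 and `"rearfoot"`
#'   for ids 13-16.
#'
#' @return A data frame of class `insole_layout`, ordered by `sensor_id`.
#' @export
insole_layout <- function(sensor_id, x, y, region) {
  lay <- data.frame(sensor_id = as.integer(sensor_id), x = as.numeric(x),
                    y = as.numeric(y), region = as.character(region),
                    stringsAsFactors = FALSE)
  validate_layout(lay)
}

N_SENSORS <- 16L
FOREFOOT_IDS <- 1:12
REARFOOT_IDS <- 13:16

validate_layout <- function(lay) {
  if (!all(c("sensor_id", "x", "y", "region") %in% names(lay)))
    stop("layout must have columns sensor_id, x, y, region")
  if (nrow(lay) != N_SENSORS)
    stop("layout must contain exactly ", N_SENSORS, " sensors, got ", nrow(lay))
  if (!setequal(lay$sensor_id, 1:N_SENSORS))
    stop("sensor_id must be exactly 1..", N_SENSORS, " with no duplicates")
  lay <- lay[order(lay$sensor_id), , drop = FALSE]
  rownames(lay) <- NULL
  if (!all(is.finite(lay$x)) || !all(is.finite(lay$y)))
    stop("layout coordinates must all be finite")
  if (anyDuplicated(lay[, c("x", "y")]))
    stop("no two sensors may share identical (x, y) coordinates")
  expected <- ifelse(lay$sensor_id %in% FOREFOOT_IDS, "forefoot", "rearfoot")
  bad <- which(lay$region != expected)
  if (length(bad))
    stop("region/id mismatch for sensor(s) ",
         paste(lay$sensor_id[bad], collapse = ", "),
         ": ids 1-12 must be forefoot, 13-16 rearfoot")
  class(lay) <- c("insole_layout", "data.frame")
  lay
}

#' Read an insole layout from YAML
#'
#' The file holds a top-level `sensors:` list of
#' `{sensor_id, x, y, region}` entries; see the bundled
#' `default_layout.yaml` for the format.
#'
#' @param path Path to a YAML layout file.
#' @return An [insole_layout()].
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  doc <- yaml::read_yaml(path)
  entries <- if (!is.null(doc$sensors)) doc$sensors else doc
  if (!length(entries)) stop("no sensor entries in layout file: ", path)
  lay <- do.call(rbind, lapply(entries, function(e) {
    # YAML 1.1 resolves a bare `y` key to boolean TRUE; accept both spellings
    if (is.null(e$y) && !is.null(e[["TRUE"]])) e$y <- e[["TRUE"]]
    if (is.null(e$sensor_id) || is.null(e$x) || is.null(e$y) ||
        is.null(e$region))
      stop("layout entry missing sensor_id/x/y/region in ", path)
    data.frame(sensor_id = as.integer(e$sensor_id), x = as.numeric(e$x),
               y = as.numeric(e$y), region = as.character(e$region))
  }))
  validate_layout(lay)
}

#' Write an insole layout to YAML
#'
#' @param layout An [insole_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  layout <- validate_layout(layout)
  rows <- lapply(seq_len(nrow(layout)), function(i)
    list(sensor_id = layout$sensor_id[i], x = layout$x[i],
         y = layout$y[i], region = layout$region[i]))
  yaml::write_yaml(list(sensors = rows), path)
  invisible(path)
}

#' The bundled default insole layout
#'
#' A plausible stand-in layout (synthetic coordinates on a right-foot
#' outline, mm, origin at the posterior-lateral heel corner): three rows
#' of four forefoot sensors and a 2x2 heel block. Real deployments should
#' load a measured layout with [read_layout()]; every coordinate-dependent
#' computation takes the layout as a parameter.
#'
#' @return An [insole_layout()].
#' @export
default_layout <- function() {
  read_layout(system.file("extdata", "default_layout.yaml",
                          package = "footstress", mustWork = TRUE))
}
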