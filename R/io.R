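# Plain-text serialisation: trajectories and feature tables as CSV, units as
# GeoJSON (WGS84), footfall matrices and partitions as delimited text.

#' Write trajectories as delimited text
#'
#' Columns: user_id, timestamp (ISO-8601 UTC), longitude, latitude.
#'
#' @param traj A `synthetic_trajectories` object or a points data.frame with
#'   columns user_id, time, lon, lat.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  pts <- if (inherits(traj, "synthetic_trajectories")) traj$points else traj
  out <- data.frame(
    user_id = pts$user_id,
    timestamp = format(pts$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    longitude = sprintf("%.8f", pts$lon),
    latitude = sprintf("%.8f", pts$lat))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write units as a GeoJSON FeatureCollection
#'
#' WGS84 lon/lat polygons; properties carry `unit_id` (and grid row/col when
#' present). Grid metadata is stored in a top-level `grid` member so a
#' round-trip preserves the generator's frame.
#'
#' @param units A `haz_units` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_units_geojson <- function(units, path) {
  feats <- lapply(seq_along(units$unit_id), function(i) {
    ring <- units$rings[[i]]
    list(
      type = "Feature",
      properties = list(unit_id = units$unit_id[i],
                        row = units$row[i], col = units$col[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(k) c(ring[k, 1], ring[k, 2])))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(units$grid_rows)) {
    fc$grid <- list(rows = units$grid_rows, cols = units$grid_cols,
                    cell_size_m = units$cell_size_m,
                    origin = as.numeric(units$origin))
  }
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read units from GeoJSON
#'
#' @param path GeoJSON FeatureCollection path (single-ring polygons with a
#'   `unit_id` property).
#' @return A `haz_units` object.
#' @export
read_units_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  feats <- fc$features
  ids <- vapply(feats, function(f) as.character(f$properties$unit_id), character(1))
  rows <- vapply(feats, function(f) as.integer(f$properties$row %||% NA), integer(1))
  cols <- vapply(feats, function(f) as.integer(f$properties$col %||% NA), integer(1))
  rings <- lapply(feats, function(f) {
    stopifnot(identical(f$geometry$type, "Polygon"))
    ring <- f$geometry$coordinates[[1L]]
    do.call(rbind, lapply(ring, function(p) c(lon = p[[1]], lat = p[[2]])))
  })
  if (anyDuplicated(ids)) stop("duplicate unit_id in GeoJSON", call. = FALSE)
  g <- fc$grid
  structure(list(unit_id = ids, row = rows, col = cols, rings = rings,
                 origin = if (!is.null(g)) unlist(g$origin),
                 cell_size_m = g$cell_size_m,
                 grid_rows = g$rows, grid_cols = g$cols),
            class = "haz_units")
}

#' Write / read the urban feature table
#'
#' Delimited text with header `unit_id, lu_0 .. lu_9, supergroup`.
#'
#' @param features Feature data.frame (see [generate_urban_features()]).
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` the data.frame with `supergroup` as factor.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", paste0("lu_", 0:9), "supergroup")
  if (!all(need %in% names(out))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out$supergroup <- factor(out$supergroup)
  out
}

#' Write / read a footfall matrix as delimited text
#'
#' First column `unit_id`, remaining columns ISO dates, integer cells.
#'
#' @param mat A [footfall_matrix()].
#' @param path File path.
#' @return `write_footfall_matrix()` returns `path` invisibly;
#'   `read_footfall_matrix()` the matrix.
#' @export
write_footfall_matrix <- function(mat, path) {
  df <- data.frame(unit_id = rownames(mat), unclass(mat), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_footfall_matrix
#' @export
read_footfall_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  footfall_matrix(m, df$unit_id, as.Date(colnames(m)))
}

#' Write a HAZ partition as delimited text
#'
#' Columns `unit_id, haz_label`; excluded units carry the sentinel label -1.
#'
#' @param partition A `haz_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  lab <- partition$labels
  utils::write.csv(data.frame(unit_id = names(lab), haz_label = unname(lab)),
                   path, row.names = FALSE)
  invisible(path)
}
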