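# Readers/writers and the core artifact containers.
#
# Spatial IDs are opaque strings throughout: French commune and zip codes
# carry leading zeros, so they are never parsed as integers.

#' Create a transition matrix
#'
#' A transition matrix is the directed crosswalk linking spatial IDs at one
#' level (`source_id`) to IDs at the next level (`target_id`). Duplicate links
#' are dropped; links are a set, so row order never matters downstream.
#'
#' @param source_id,target_id character vectors of equal length; non-empty IDs.
#' @param k integer index of the matrix in the chain (1-based).
#' @return a `transition_matrix`: a data.frame with columns `source_id`,
#'   `target_id` and attribute `k`.
#' @export
transition_matrix <- function(source_id, target_id, k = 1L) {
  source_id <- as.character(source_id)
  target_id <- as.character(target_id)
  if (length(source_id) != length(target_id)) stop("source/target length mismatch")
  if (length(source_id) == 0L) stop("empty matrix")
  bad <- which(is.na(source_id) | is.na(target_id) |
                 !nzchar(trimws(source_id)) | !nzchar(trimws(target_id)))
  if (length(bad)) stop(sprintf("malformed link at row %d: blank ID", bad[1]))
  df <- unique(data.frame(source_id = trimws(source_id),
                          target_id = trimws(target_id),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  attr(df, "k") <- as.integer(k)
  class(df) <- c("transition_matrix", "data.frame")
  df
}

#' Read a transition matrix from CSV
#'
#' Expects a UTF-8 CSV with header `source_id,target_id`. Rows are
#' de-duplicated (set semantics); blank IDs are an error naming the offending
#' line.
#'
#' @param path path to the CSV file.
#' @param k integer chain index of the matrix.
#' @return a [transition_matrix].
#' @export
read_transition_matrix <- function(path, k = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty matrix: %s", path))
  if (!all(c("source_id", "target_id") %in% names(df))) {
    stop("expected header 'source_id,target_id'")
  }
  blank <- which(!nzchar(trimws(df$source_id)) | !nzchar(trimws(df$target_id)))
  if (length(blank)) {
    stop(sprintf("malformed link in %s at line %d: blank ID", path, blank[1] + 1L))
  }
  transition_matrix(df$source_id, df$target_id, k = k)
}

#' Write a transition matrix to CSV
#'
#' @param m a [transition_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m)[, c("source_id", "target_id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- aggregated tables -----------------------------------------------------

#' Create an aggregated table
#'
#' Per-spatial-unit variable values plus metadata saying how each variable may
#' be aggregated. `var_meta` is a named list, one entry per variable, each a
#' list with `kind` (`"count"`, `"continuous"` or `"proportion"`) and
#' optionally `weight_var`. Counts must be non-negative integers; proportions
#' must lie in [0, 1]. Missing cells stay `NA` (absent), never zero.
#'
#' @param df data.frame with an `id` column plus one column per variable.
#' @param var_meta named list of variable metadata; variables not listed
#'   default to `kind = "continuous"`.
#' @param level optional integer level tag (1 = finest/ecological).
#' @return an `aggregated_table` (a data.frame with attributes `var_meta` and
#'   `level`).
#' @export
aggregated_table <- function(df, var_meta = list(), level = NA_integer_) {
  if (!"id" %in% names(df)) stop("missing 'id' column")
  df$id <- as.character(df$id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop(sprintf("duplicate spatial unit: %s", dup[1]))
  vars <- setdiff(names(df), "id")
  for (v in vars) {
    meta <- var_meta[[v]]
    kind <- if (is.null(meta$kind)) "continuous" else meta$kind
    vals <- suppressWarnings(as.numeric(df[[v]]))
    if (kind == "count") {
      ok <- is.na(vals) | (vals >= 0 & abs(vals - round(vals)) < 1e-8)
      if (!all(ok)) stop(sprintf("invalid count in variable '%s' (unit %s)",
                                 v, df$id[which(!ok)[1]]))
      vals <- round(vals)
    } else if (kind == "proportion") {
      ok <- is.na(vals) | (vals >= 0 & vals <= 1)
      if (!all(ok)) stop(sprintf("proportion out of range in variable '%s' (unit %s)",
                                 v, df$id[which(!ok)[1]]))
    }
    df[[v]] <- vals
    if (is.null(var_meta[[v]])) var_meta[[v]] <- list(kind = kind)
  }
  rownames(df) <- NULL
  attr(df, "var_meta") <- var_meta
  attr(df, "level") <- as.integer(level)
  class(df) <- c("aggregated_table", "data.frame")
  df
}

#' Read an aggregated table from CSV
#'
#' Expects a CSV with header `id,<var1>,<var2>,...`. Values are typed and
#' checked against `var_meta`; empty cells are recorded as missing, not zero.
#'
#' @inheritParams aggregated_table
#' @param path path to the CSV file.
#' @return an [aggregated_table].
#' @export
read_aggregated_table <- function(path, var_meta = list(), level = NA_integer_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  aggregated_table(df, var_meta = var_meta, level = level)
}

#' Write an aggregated table to CSV
#'
#' @param tab an [aggregated_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aggregated_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read variable metadata from a YAML file
#'
#' The YAML maps variable names to `kind` (and optional `weight_var`, `tag`).
#'
#' @param path YAML file path.
#' @return named list usable as `var_meta`.
#' @export
read_var_meta <- function(path) {
  yaml::read_yaml(path)
}

# ---- geometries ------------------------------------------------------------

#' Create a geometry table
#'
#' @param geoms named list of multipolygons (see `R/geometry.R` for the
#'   representation); names are spatial IDs.
#' @return a `geom_table`: list with `ids`, `geoms`, `areas` (km^2).
#' @export
geom_table <- function(geoms) {
  ids <- names(geoms)
  if (is.null(ids) || any(!nzchar(ids))) stop("geometries must be named by spatial ID")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(sprintf("duplicate geometry id: %s", dup[1]))
  areas <- vapply(geoms, multipolygon_area, numeric(1))
  if (any(areas <= 0)) {
    stop(sprintf("zero-area geometry: %s", ids[which(areas <= 0)[1]]))
  }
  structure(list(ids = ids, geoms = geoms, areas = areas), class = "geom_table")
}

#' @export
print.geom_table <- function(x, ...) {
  cat(sprintf("<geom_table> %d units, median area %.3g km^2\n",
              length(x$ids), stats::median(x$areas)))
  invisible(x)
}

geojson_coords_to_mp <- function(geometry) {
  ring_mat <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    # GeoJSON rings repeat the first vertex; drop the closure
    if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12)) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  type <- geometry$type
  if (identical(type, "Polygon")) {
    list(lapply(geometry$coordinates, ring_mat))
  } else if (identical(type, "MultiPolygon")) {
    lapply(geometry$coordinates, function(poly) lapply(poly, ring_mat))
  } else {
    stop(sprintf("unsupported geometry type: %s", type))
  }
}

#' Read geometries from a GeoJSON FeatureCollection
#'
#' Each feature must carry an `id` property. Coordinates are assumed to be in
#' a planar projected CRS in km; areas are computed with the planar shoelace
#' formula, in km^2. Zero-area or unnamed features are an error.
#'
#' @param path GeoJSON file path.
#' @return a [geom_table].
#' @export
read_geometries <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a FeatureCollection")
  geoms <- list()
  for (f in gj$features) {
    id <- f$properties$id
    if (is.null(id) || !nzchar(as.character(id))) stop("feature missing 'id' property")
    id <- as.character(id)
    if (!is.null(geoms[[id]])) stop(sprintf("duplicate geometry id: %s", id))
    geoms[[id]] <- geojson_coords_to_mp(f$geometry)
  }
  geom_table(geoms)
}

mp_to_geojson_coords <- function(mp) {
  lapply(mp, function(part) {
    lapply(part, function(ring) {
      closed <- rbind(ring, ring[1, , drop = FALSE])
      lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
    })
  })
}

#' Write a geometry table as GeoJSON
#'
#' Emits a FeatureCollection of MultiPolygons with an `id` property per
#' feature, consumable by any GIS.
#'
#' @param gt a [geom_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometries <- function(gt, path) {
  features <- lapply(gt$ids, function(id) {
    list(type = "Feature",
         properties = list(id = id),
         geometry = list(type = "MultiPolygon",
                         coordinates = mp_to_geojson_coords(gt$geoms[[id]])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
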