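# Pipeline orchestration: the functions behind the command-line interface.

#' Read a run configuration from YAML
#'
#' Recognised fields: `matrices` (paths in chain order), `eco_table`,
#' `med_table`, `var_meta` (YAML path), `fine_geojson`, `medical_geojson`,
#' `base` (`"medical"`/`"eco"` override), `aggregation` (list of
#' variable/method/weight_var), `references` (named, each with
#' `median_area_km2` and optional `median_population`), `out`, `seed`, and a
#' `simulate` block of [geography_params()] fields.
#'
#' @param path YAML config path.
#' @return the config list, with `seed` defaulting to 1.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Read a mapping table back from its CSV
#'
#' Reconstructs the `analysis_units` and `eco_to_analysis` attributes from
#' the `medical_id`/`analysis_id` and `eco_id`/`analysis_id` columns.
#'
#' @param path CSV written by [write_mapping_table()].
#' @return a mapping table usable by [aggregate_to_analysis()] and
#'   [dissolve()].
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  need <- c("eco_id", "medical_id", "analysis_id")
  if (!all(need %in% names(df))) stop("not a mapping table CSV")
  pairs <- unique(df[, c("medical_id", "analysis_id")])
  units <- split(pairs$medical_id, pairs$analysis_id)
  attr(df, "analysis_units") <- lapply(units, sort)
  eco <- unique(df[, c("eco_id", "analysis_id")])
  attr(df, "eco_to_analysis") <- stats::setNames(eco$analysis_id, eco$eco_id)
  class(df) <- c("mapping_table", "data.frame")
  df
}

load_matrices <- function(cfg) {
  if (is.null(cfg$matrices) || length(cfg$matrices) < 1L) {
    stop("config lists no transition matrices")
  }
  lapply(seq_along(cfg$matrices), function(i) {
    read_transition_matrix(cfg$matrices[[i]], k = i)
  })
}

#' Build the mapping table from a config and write the outputs
#'
#' Writes `mapping.csv` and `census.json` into the configured output
#' directory.
#'
#' @param config list from [read_run_config()] (or built in code).
#' @return the mapping table, invisibly.
#' @export
run_build <- function(config) {
  out <- if (is.null(config$out)) "." else config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  matrices <- load_matrices(config)
  mt <- build_mapping_table(matrices)
  write_mapping_table(mt, file.path(out, "mapping.csv"),
                      census_path = file.path(out, "census.json"))
  message(sprintf("mapping table: %d analysis units written to %s",
                  length(attr(mt, "analysis_units")), file.path(out, "mapping.csv")))
  invisible(mt)
}

#' Validate a built mapping table from a config
#'
#' Aggregates both databases to the analysis scale, compares the shared
#' variable(s), and — when geometries are configured — dissolves the fine
#' geometries and computes the spatial report. Writes `comparison.json`,
#' `per_unit.csv`, and when possible `spatial.json` plus
#' `analysis.geojson`.
#'
#' @param config list from [read_run_config()].
#' @param mapping optional mapping table; by default `mapping.csv` under
#'   `config$out` is read.
#' @return list with `comparison` and (possibly NULL) `spatial`, invisibly.
#' @export
run_validate <- function(config, mapping = NULL) {
  out <- if (is.null(config$out)) "." else config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(mapping)) {
    mapping <- read_mapping_table(file.path(out, "mapping.csv"))
  }
  meta <- if (!is.null(config$var_meta)) read_var_meta(config$var_meta) else list()
  eco <- read_aggregated_table(config$eco_table, var_meta = meta, level = 1L)
  med <- read_aggregated_table(config$med_table, var_meta = meta)
  common <- select_common_variables(meta, meta, eco, med)
  comparison <- NULL
  if (nrow(common) > 0L) {
    v <- common$variable_eco[1]
    spec <- list(aggregation_spec(v, "sum"))
    eco_a <- aggregate_to_analysis(eco, mapping, spec)
    med_a <- aggregate_to_analysis(med, mapping, spec)
    comparison <- compare_common_variable(eco_a, med_a, v)
    write_comparison_report(comparison, file.path(out, "comparison.json"),
                            per_unit_path = file.path(out, "per_unit.csv"))
  } else {
    message("no common variable; comparison skipped")
  }
  spatial <- NULL
  if (!is.null(config$fine_geojson) && file.exists(config$fine_geojson)) {
    fine <- read_geometries(config$fine_geojson)
    dg <- dissolve(fine, mapping)
    refs <- if (is.null(config$references)) list() else config$references
    spatial <- spatial_validation(dg, initial_median_km2 = stats::median(fine$areas),
                                  references = refs)
    write_spatial_report(spatial, file.path(out, "spatial.json"))
    write_geometries(dg, file.path(out, "analysis.geojson"))
  } else {
    message("no geometries configured; spatial validation skipped")
  }
  invisible(list(comparison = comparison, spatial = spatial))
}

#' Generate a synthetic fixture set from a config
#'
#' The `simulate` block of the config supplies [geography_params()] fields;
#' the config `seed` is used unless the block overrides it.
#'
#' @param config list from [read_run_config()].
#' @return the fixture directory, invisibly.
#' @export
run_simulate <- function(config) {
  out <- if (is.null(config$out)) "." else config$out
  sim <- if (is.null(config$simulate)) list() else config$simulate
  if (is.null(sim$seed)) sim$seed <- config$seed
  params <- do.call(geography_params, sim)
  geo <- generate_geography(params)
  counts <- generate_counts(geo, params)
  write_fixtures(geo, counts, out)
  message(sprintf("fixtures written to %s (seed %d)", out, params$seed))
  invisible(out)
}
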