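# Spatial validation: dissolved analysis geometries, fragmentation, centroid
# containment and the spatial-resolution decline index.

#' Dissolve member geometries into analysis-unit geometries
#'
#' Each analysis unit's geometry is the union of its members' geometries.
#' Members sharing a boundary of positive length are merged into a single
#' polygon (internal borders cancel); disjoint or corner-touching members
#' stay separate parts of a multipolygon. Area is additive for
#' non-overlapping members. Geometry IDs may sit at the ecological or the
#' medical level, whichever the mapping covers; IDs lacking a geometry are
#' reported via the `missing_geometry` attribute.
#'
#' @param geoms a [geom_table] at the ecological or medical level.
#' @param mapping a mapping table from [build_mapping_table()].
#' @param tol snap tolerance (coordinate units) for shared-boundary tests.
#' @return a [geom_table] at the analysis level.
#' @export
dissolve <- function(geoms, mapping, tol = 1e-9) {
  memb <- resolve_membership(geoms$ids, mapping)
  units <- attr(mapping, "analysis_units")
  by_unit <- split(geoms$ids[!is.na(memb$analysis_id)],
                   memb$analysis_id[!is.na(memb$analysis_id)])
  all_units <- names(units)
  no_geom <- setdiff(all_units, names(by_unit))
  if (length(no_geom)) {
    stop(sprintf("no member geometries for analysis unit %s", no_geom[1]))
  }
  out <- lapply(by_unit, function(ids) {
    parts <- unlist(lapply(geoms$geoms[ids], identity), recursive = FALSE)
    union_parts(parts, tol)
  })
  gt <- geom_table(out)
  attr(gt, "missing_geometry") <- memb$unmapped
  gt
}

#' Fragmentation index
#'
#' A spatial unit is fragmented (discontinuous) when its territory has more
#' than one connected part, where parts touching only at a single point count
#' as separate: one cannot move between them without leaving the unit. The
#' index is the number of fragmented units as a proportion of all units.
#'
#' @param geoms a [geom_table] (normally the dissolved analysis geometries).
#' @param tol shared-boundary snap tolerance.
#' @return list with `n_units`, `n_fragmented`, `pct` (0-100, full
#'   precision), and `fragmented_ids`.
#' @export
fragmentation_index <- function(geoms, tol = 1e-9) {
  if (length(geoms$ids) == 0L) stop("empty geometry table")
  frag <- vapply(geoms$geoms, function(mp) {
    if (length(mp) <= 1L) return(FALSE)
    max(rook_components(mp, tol)) > 1L
  }, logical(1))
  list(n_units = length(frag),
       n_fragmented = sum(frag),
       pct = 100 * sum(frag) / length(frag),
       fragmented_ids = sort(geoms$ids[frag]))
}

#' Centroid containment
#'
#' Flags units whose area centroid falls outside the unit itself — the
#' classic hazard of fragmented units, whose aggregated data are often
#' represented by a centroid lying in the gap between parts. A centroid on
#' the boundary counts as inside.
#'
#' @param geoms a [geom_table].
#' @param tol boundary snap tolerance.
#' @return list with `n_outside`, `outside_ids`, and per-unit logical
#'   `outside`.
#' @export
centroid_containment <- function(geoms, tol = 1e-9) {
  if (length(geoms$ids) == 0L) stop("empty geometry table")
  outside <- vapply(geoms$geoms, function(mp) {
    c0 <- multipolygon_centroid(mp)
    !point_in_multipolygon(c0, mp, tol)
  }, logical(1))
  list(n_outside = sum(outside),
       outside_ids = sort(geoms$ids[outside]),
       outside = outside)
}

#' Spatial-resolution decline index
#'
#' Ratio of the median unit size of a target scale to that of the finest
#' initial scale (surface area in km^2, or population). The analysis scale's
#' ratio is compared with the same ratio for coarser administrative reference
#' units; a smaller index means a finer spatial resolution.
#'
#' @param median_target,median_initial positive medians on the same scale
#'   (km^2 or inhabitants).
#' @return the ratio `median_target / median_initial`.
#' @export
resolution_decline_index <- function(median_target, median_initial) {
  if (!is.finite(median_target) || !is.finite(median_initial) ||
      median_target <= 0 || median_initial <= 0) {
    stop("decline index requires positive medians")
  }
  median_target / median_initial
}

#' Full spatial validation report
#'
#' Combines the fragmentation index, centroid containment and the decline
#' index of the analysis scale against the finest initial scale and any
#' configured reference units.
#'
#' @param analysis_geoms dissolved [geom_table] at the analysis level.
#' @param initial_median_km2 median area of the finest initial spatial unit.
#' @param references optional named list of reference units, each a list with
#'   `median_area_km2` and optionally `median_population`.
#' @param analysis_median_population,initial_median_population optional
#'   population medians for the population-based index.
#' @return a `spatial_report` list.
#' @export
spatial_validation <- function(analysis_geoms, initial_median_km2,
                               references = list(),
                               analysis_median_population = NULL,
                               initial_median_population = NULL) {
  frag <- fragmentation_index(analysis_geoms)
  cent <- centroid_containment(analysis_geoms)
  med_area <- stats::median(analysis_geoms$areas)
  iqr_area <- stats::quantile(analysis_geoms$areas, c(0.25, 0.75), type = 7,
                              names = FALSE)
  decline <- list(analysis = list(
    surface_ratio = resolution_decline_index(med_area, initial_median_km2)))
  if (!is.null(analysis_median_population) && !is.null(initial_median_population)) {
    decline$analysis$population_ratio <-
      resolution_decline_index(analysis_median_population, initial_median_population)
  }
  for (nm in names(references)) {
    ref <- references[[nm]]
    d <- list(surface_ratio = resolution_decline_index(ref$median_area_km2,
                                                       initial_median_km2))
    if (!is.null(ref$median_population) && !is.null(initial_median_population)) {
      d$population_ratio <- resolution_decline_index(ref$median_population,
                                                     initial_median_population)
    }
    d$analysis_is_finer <- decline$analysis$surface_ratio < d$surface_ratio
    decline[[nm]] <- d
  }
  structure(list(
    n_units = frag$n_units,
    n_fragmented = frag$n_fragmented,
    fragmentation_pct = frag$pct,
    fragmented_ids = frag$fragmented_ids,
    n_centroid_outside = cent$n_outside,
    centroid_outside_ids = cent$outside_ids,
    median_area_km2 = med_area,
    iqr_area = c(q1 = iqr_area[1], q3 = iqr_area[2]),
    decline_indices = decline
  ), class = "spatial_report")
}

#' @export
print.spatial_report <- function(x, ...) {
  cat(sprintf("<spatial_report> %d analysis units\n", x$n_units))
  cat(sprintf("  fragmentation: %.1f%% (n = %d); centroid outside: %d\n",
              x$fragmentation_pct, x$n_fragmented, x$n_centroid_outside))
  cat(sprintf("  median area %.1f km^2 [%.1f; %.1f]\n",
              x$median_area_km2, x$iqr_area[1], x$iqr_area[2]))
  for (nm in setdiff(names(x$decline_indices), "analysis")) {
    cat(sprintf("  decline index vs %s: %.1f (analysis %.1f)\n", nm,
                x$decline_indices[[nm]]$surface_ratio,
                x$decline_indices$analysis$surface_ratio))
  }
  invisible(x)
}

#' Write a spatial report as JSON
#'
#' @param report a [spatial_validation()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spatial_report <- function(report, path) {
  payload <- unclass(report)
  payload$iqr_area <- as.list(report$iqr_area)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
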