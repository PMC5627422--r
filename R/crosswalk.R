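# Building the mapping table.
#
# The method never disaggregates: when spatial units overlap, they are merged
# into a larger analysis unit until every ecological unit maps to exactly one
# analysis unit. The chain of transition matrices M_1..M_p runs from the
# ecological ID system (level 1) through temporary IDs to the medical ID
# system (level p + 1).

#' Choose the direction of the relationship
#'
#' The database whose spatial units have the larger median surface area seeds
#' the analysis units; aggregating towards the smaller one would require
#' disaggregation, which this method rules out.
#'
#' @param areas_med,areas_eco numeric vectors of unit areas (km^2), or
#'   [geom_table] objects.
#' @return list with `base` (`"medical"` or `"eco"`), `median_med`,
#'   `median_eco`.
#' @export
choose_direction <- function(areas_med, areas_eco) {
  if (inherits(areas_med, "geom_table")) areas_med <- areas_med$areas
  if (inherits(areas_eco, "geom_table")) areas_eco <- areas_eco$areas
  if (length(areas_med) == 0L || length(areas_eco) == 0L) stop("empty area set")
  m_med <- stats::median(areas_med)
  m_eco <- stats::median(areas_eco)
  if (m_med == m_eco) {
    stop("ambiguous direction; specify base explicitly in config")
  }
  list(base = if (m_med > m_eco) "medical" else "eco",
       median_med = m_med, median_eco = m_eco)
}

#' Classify the equivalence situations of a transition matrix
#'
#' Connected components of the bipartite source/target link graph, each
#' labelled by its cardinality pattern: `one_to_one` (1 source, 1 target),
#' `many_to_one` (n, 1), `one_to_many` (1, n) or `many_to_many` (n, m). The
#' four labels are mutually exclusive and exhaustive, and the components
#' partition the matrix's links.
#'
#' @param m a [transition_matrix].
#' @return data.frame with one row per component: `component`, `situation`,
#'   `n_sources`, `n_targets`, `n_links`, plus list-columns `sources`,
#'   `targets`.
#' @export
classify_components <- function(m) {
  if (nrow(m) == 0L) stop("empty matrix")
  src <- paste0("S\r", m$source_id)  # level prefix avoids ID collisions
  tgt <- paste0("T\r", m$target_id)
  g <- igraph::graph_from_data_frame(data.frame(from = src, to = tgt), directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_link <- memb[src]
  out <- lapply(sort(unique(memb)), function(cid) {
    rows <- comp_of_link == cid
    s <- unique(m$source_id[rows])
    t <- unique(m$target_id[rows])
    situation <- if (length(s) == 1L && length(t) == 1L) "one_to_one"
    else if (length(t) == 1L) "many_to_one"
    else if (length(s) == 1L) "one_to_many"
    else "many_to_many"
    list(component = cid, situation = situation,
         n_sources = length(s), n_targets = length(t), n_links = sum(rows),
         sources = list(sort(s)), targets = list(sort(t)))
  })
  df <- do.call(rbind, lapply(out, function(r) {
    data.frame(component = r$component, situation = r$situation,
               n_sources = r$n_sources, n_targets = r$n_targets,
               n_links = r$n_links, stringsAsFactors = FALSE)
  }))
  df$sources <- lapply(out, function(r) r$sources[[1]])
  df$targets <- lapply(out, function(r) r$targets[[1]])
  df$component <- seq_len(nrow(df))
  df
}

#' Compose a chain of transition matrices into an eco-medical linkage
#'
#' An ecological ID and a medical ID are linked iff a path exists through all
#' p matrices. With p = 1 the linkage equals the matrix itself. IDs present as
#' targets of M_k but absent from the sources of M_{k+1} (and vice versa) are
#' dangling: they are dropped from the linkage but reported via the
#' `dangling` attribute and a warning, never silently.
#'
#' @param matrices list of [transition_matrix] objects in chain order.
#' @return a `linkage_graph`: data.frame with columns `eco_id`, `medical_id`,
#'   attributes `paths` (the full level-by-level paths) and `dangling`.
#' @export
compose_matrices <- function(matrices) {
  p <- length(matrices)
  if (p < 1L) stop("need at least one transition matrix")
  ks <- vapply(matrices, function(m) attr(m, "k"), integer(1))
  if (any(diff(ks) != 1L)) stop("chain break: matrix indices are not consecutive")
  paths <- data.frame(level1 = matrices[[1]]$source_id,
                      level2 = matrices[[1]]$target_id,
                      stringsAsFactors = FALSE)
  dangling <- list()
  if (p > 1L) {
    for (k in 2:p) {
      m <- matrices[[k]]
      prev_col <- paste0("level", k)
      lost_fwd <- setdiff(unique(paths[[prev_col]]), unique(m$source_id))
      lost_bwd <- setdiff(unique(m$source_id), unique(paths[[prev_col]]))
      if (length(lost_fwd) || length(lost_bwd)) {
        dangling[[paste0("M", k)]] <- list(targets_without_source = sort(lost_fwd),
                                           sources_without_target = sort(lost_bwd))
        warning(sprintf("dangling ID(s) between M%d and M%d: %s", k - 1L, k,
                        paste(sort(c(lost_fwd, lost_bwd)), collapse = ", ")))
      }
      names(m)[names(m) == "source_id"] <- prev_col
      names(m)[names(m) == "target_id"] <- paste0("level", k + 1L)
      paths <- merge(paths, as.data.frame(m), by = prev_col, sort = FALSE)
      paths <- paths[, paste0("level", seq_len(k + 1L)), drop = FALSE]
    }
  }
  paths <- unique(paths)
  rownames(paths) <- NULL
  g <- unique(data.frame(eco_id = paths$level1,
                         medical_id = paths[[paste0("level", p + 1L)]],
                         stringsAsFactors = FALSE))
  g <- g[order(g$eco_id, g$medical_id), ]
  rownames(g) <- NULL
  attr(g, "paths") <- paths
  attr(g, "dangling") <- dangling
  class(g) <- c("linkage_graph", "data.frame")
  g
}

#' Merge overlapping medical units into analysis units
#'
#' Medical IDs that share at least one ecological ID (directly or through a
#' chain of shared units, transitively) are aggregated into a single analysis
#' unit. This is the step that guarantees every ecological unit maps to
#' exactly one analysis unit, so no value ever needs to be disaggregated.
#' When no overlap exists, analysis units coincide with medical units.
#'
#' Analysis IDs are named by joining the sorted member medical IDs with
#' `"+"`, so they are deterministic and traceable.
#'
#' @param g a linkage graph from [compose_matrices()] (or any data.frame with
#'   `eco_id`, `medical_id`).
#' @return a `mapping_table`: data.frame with columns `eco_id`,
#'   intermediate `level*` columns when available, `medical_id`,
#'   `analysis_id`, `situation`; attribute `analysis_units` is the named list
#'   analysis_id -> member medical IDs.
#' @export
merge_overlapping <- function(g) {
  if (nrow(g) == 0L) stop("empty linkage graph")
  med <- unique(g$medical_id)
  # bipartite eco-medical graph: medical units sharing an eco unit are in the
  # same connected component
  gb <- igraph::graph_from_data_frame(
    data.frame(from = paste0("E\r", g$eco_id), to = paste0("M\r", g$medical_id)),
    directed = FALSE)
  memb <- igraph::components(gb)$membership
  med_comp <- memb[paste0("M\r", med)]
  units <- split(med, med_comp)
  unit_name <- vapply(units, function(ms) paste(sort(ms), collapse = "+"), character(1))
  med_to_analysis <- stats::setNames(rep(unit_name, lengths(units)), unlist(units))
  analysis_units <- stats::setNames(lapply(units, sort), unit_name)

  rows <- attr(g, "paths")
  if (is.null(rows)) {
    rows <- data.frame(eco_id = g$eco_id, medical_id = g$medical_id,
                       stringsAsFactors = FALSE)
  } else {
    names(rows)[1] <- "eco_id"
    names(rows)[ncol(rows)] <- "medical_id"
  }
  rows$analysis_id <- unname(med_to_analysis[rows$medical_id])
  merged <- names(analysis_units)[lengths(analysis_units) > 1L]
  # per-row situation: overlap merge dominates; otherwise the cardinality
  # pattern of the row's eco<->medical component
  eco_med <- unique(data.frame(eco_id = g$eco_id, medical_id = g$medical_id,
                               analysis_id = unname(med_to_analysis[g$medical_id]),
                               stringsAsFactors = FALSE))
  card <- function(aid) {
    sel <- eco_med$analysis_id == aid
    ne <- length(unique(eco_med$eco_id[sel]))
    nm <- length(unique(eco_med$medical_id[sel]))
    if (nm > 1L) "overlap_merge"
    else if (ne == 1L) "one_to_one"
    else "many_to_one"
  }
  sit <- vapply(names(analysis_units), card, character(1))
  rows$situation <- unname(sit[rows$analysis_id])
  rows <- rows[order(rows$eco_id, rows$medical_id), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "analysis_units") <- analysis_units
  attr(rows, "eco_to_analysis") <- stats::setNames(
    eco_med$analysis_id[!duplicated(eco_med$eco_id)],
    eco_med$eco_id[!duplicated(eco_med$eco_id)])
  attr(rows, "dangling") <- attr(g, "dangling")
  class(rows) <- c("mapping_table", "data.frame")
  rows
}

#' Build the full mapping table from a chain of transition matrices
#'
#' Orchestrates the whole construction: classify each matrix's equivalence
#' situations, compose the chain into an eco-medical linkage, and merge
#' overlapping medical units into analysis units. Also returns a situation
#' census: per matrix, the count and percentage of links falling in each
#' cardinality pattern, plus the number of overlap merges performed.
#'
#' @param matrices list of [transition_matrix] objects in chain order.
#' @return the [merge_overlapping()] mapping table, with an extra `census`
#'   attribute.
#' @export
build_mapping_table <- function(matrices) {
  census <- list()
  for (i in seq_along(matrices)) {
    comps <- classify_components(matrices[[i]])
    tot <- sum(comps$n_links)
    by_sit <- lapply(c("one_to_one", "many_to_one", "one_to_many", "many_to_many"),
                     function(s) {
                       n <- sum(comps$n_links[comps$situation == s])
                       list(links = n, pct = 100 * n / tot,
                            components = sum(comps$situation == s))
                     })
    names(by_sit) <- c("one_to_one", "many_to_one", "one_to_many", "many_to_many")
    census[[paste0("M", attr(matrices[[i]], "k"))]] <- by_sit
  }
  g <- compose_matrices(matrices)
  mt <- merge_overlapping(g)
  units <- attr(mt, "analysis_units")
  merged <- units[lengths(units) > 1L]
  census$overlap_merges <- list(
    merged_medical_ids = sum(lengths(merged)),
    analysis_units_created = length(merged))
  census$n_analysis_units <- length(units)
  attr(mt, "census") <- census
  mt
}

#' @export
print.mapping_table <- function(x, ...) {
  units <- attr(x, "analysis_units")
  merged <- sum(lengths(units) > 1L)
  cat(sprintf("<mapping_table> %d eco units -> %d analysis units (%d merged from overlaps)\n",
              length(unique(x$eco_id)), length(units), merged))
  invisible(x)
}

#' Write a mapping table to CSV (plus its census as JSON)
#'
#' @param mt a mapping table.
#' @param path CSV output path; the census, when present, goes to
#'   `census_path`.
#' @param census_path optional JSON path for the situation census.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(mt, path, census_path = NULL) {
  utils::write.csv(as.data.frame(mt), path, row.names = FALSE, quote = FALSE)
  if (!is.null(census_path) && !is.null(attr(mt, "census"))) {
    jsonlite::write_json(attr(mt, "census"), census_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
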