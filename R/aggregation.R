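# Aggregating variables to the analysis scale through the mapping table.

#' Declare how a variable is aggregated
#'
#' Count variables only admit `sum` (counts of events are additive and
#' anything else would mis-state them); continuous variables and proportions
#' admit `mean`, `median` and `weighted_mean`. `weighted_mean` needs a
#' `weight_var` naming another variable in the same table (typically a
#' population denominator).
#'
#' @param variable variable name.
#' @param method one of `"sum"`, `"mean"`, `"median"`, `"weighted_mean"`.
#' @param weight_var weight variable name; required iff `method` is
#'   `"weighted_mean"`.
#' @return an `aggregation_spec` list.
#' @export
aggregation_spec <- function(variable, method = c("sum", "mean", "median", "weighted_mean"),
                             weight_var = NULL) {
  method <- match.arg(method)
  if (method == "weighted_mean" && is.null(weight_var)) {
    stop("weighted_mean requires a weight_var")
  }
  structure(list(variable = variable, method = method, weight_var = weight_var),
            class = "aggregation_spec")
}

# map table ids to analysis ids; the table can sit at the eco level or the
# medical level, whichever the mapping covers
resolve_membership <- function(ids, mapping) {
  eco_map <- attr(mapping, "eco_to_analysis")
  units <- attr(mapping, "analysis_units")
  med_map <- stats::setNames(rep(names(units), lengths(units)), unlist(units))
  n_eco <- sum(ids %in% names(eco_map))
  n_med <- sum(ids %in% names(med_map))
  map <- if (n_eco >= n_med) eco_map else med_map
  list(analysis_id = unname(map[ids]),
       unmapped = sort(ids[!ids %in% names(map)]),
       level = if (n_eco >= n_med) "eco" else "medical")
}

#' Aggregate a table to the analysis scale
#'
#' One output row per analysis unit. Sums conserve totals exactly over mapped
#' units; weighted means use sum(v*w)/sum(w) over member units. Member units
#' with a missing value are excluded from mean/median/weighted mean; for a
#' sum the unit's total is still computed over the present members but the
#' unit is flagged incomplete in the report — undercounting is what the
#' validation step must detect, so it is never masked by imputation. Units in
#' the table but absent from the mapping are listed in the report, not
#' aggregated.
#'
#' @param tab an [aggregated_table] at the ecological or medical level.
#' @param mapping a mapping table from [build_mapping_table()].
#' @param specs list of [aggregation_spec] objects.
#' @return an [aggregated_table] at the analysis level, with a `report`
#'   attribute (`unmapped`, `incomplete` per variable, `level`).
#' @export
aggregate_to_analysis <- function(tab, mapping, specs) {
  var_meta <- attr(tab, "var_meta")
  memb <- resolve_membership(tab$id, mapping)
  keep <- !is.na(memb$analysis_id)
  aid <- memb$analysis_id[keep]
  sub <- as.data.frame(tab)[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no table unit is covered by the mapping")
  out_ids <- sort(unique(aid))
  out <- data.frame(id = out_ids, stringsAsFactors = FALSE)
  report <- list(level = memb$level, unmapped = memb$unmapped, incomplete = list())
  out_meta <- list()
  for (spec in specs) {
    v <- spec$variable
    if (!v %in% names(sub)) stop(sprintf("variable '%s' not in table", v))
    kind <- if (is.null(var_meta[[v]]$kind)) "continuous" else var_meta[[v]]$kind
    if (kind == "count" && spec$method != "sum") {
      stop(sprintf("count variable '%s' only allows sum aggregation", v))
    }
    if (kind == "proportion" && spec$method == "sum") {
      stop(sprintf("sum aggregation is invalid for proportion variable '%s'", v))
    }
    vals <- split(sub[[v]], aid)
    if (spec$method == "sum") {
      agg <- vapply(vals, function(x) sum(x, na.rm = TRUE), numeric(1))
      incomplete <- names(vals)[vapply(vals, anyNA, logical(1))]
      if (length(incomplete)) report$incomplete[[v]] <- incomplete
    } else if (spec$method == "mean") {
      agg <- vapply(vals, function(x) mean(x, na.rm = TRUE), numeric(1))
    } else if (spec$method == "median") {
      # even member counts: midpoint of the two central values (type 7)
      agg <- vapply(vals, function(x) stats::median(x, na.rm = TRUE), numeric(1))
    } else {
      w <- split(sub[[spec$weight_var]], aid)
      agg <- vapply(seq_along(vals), function(i) {
        x <- vals[[i]]; wi <- w[[i]]
        ok <- !is.na(x) & !is.na(wi)
        if (sum(wi[ok]) == 0) {
          stop(sprintf("zero total weight in analysis unit %s for variable '%s'",
                       names(vals)[i], v))
        }
        sum(x[ok] * wi[ok]) / sum(wi[ok])
      }, numeric(1))
      names(agg) <- names(vals)
    }
    out[[v]] <- unname(agg[out$id])
    out_meta[[v]] <- var_meta[[v]]
  }
  res <- aggregated_table(out, var_meta = out_meta, level = NA_integer_)
  attr(res, "report") <- report
  res
}
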