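# Validating the mapping table with a variable common to both databases.

#' Compare a common variable between the two databases at the analysis scale
#'
#' For every analysis unit i with a positive medical value, the relative
#' difference is r_i = 100 * (eco_i - med_i) / med_i: the medical count is the
#' denominator. Units with a zero medical value are excluded from the
#' per-unit statistics and counted in `n_excluded`. Both signed and absolute
#' summaries are reported; quartiles use linear interpolation between order
#' statistics (type 7), which the IQR values depend on.
#'
#' @param eco_agg,med_agg [aggregated_table]s at the analysis level.
#' @param variable the shared variable name.
#' @return a `comparison_report`: list with `per_unit` (data.frame
#'   `analysis_id`, `eco`, `med`, `rel_diff_pct`), `median_pct`, `iqr_pct`
#'   (q1, q3), `median_abs_pct`, `iqr_abs_pct`, `total_eco`, `total_med`,
#'   `total_difference`, `n_units`, `n_excluded`.
#' @export
compare_common_variable <- function(eco_agg, med_agg, variable) {
  if (!variable %in% names(eco_agg)) stop(sprintf("variable '%s' absent from eco table", variable))
  if (!variable %in% names(med_agg)) stop(sprintf("variable '%s' absent from medical table", variable))
  ids <- intersect(eco_agg$id, med_agg$id)
  if (length(ids) == 0L) stop("empty comparison: no overlapping analysis ids")
  e <- eco_agg[[variable]][match(ids, eco_agg$id)]
  m <- med_agg[[variable]][match(ids, med_agg$id)]
  ok <- !is.na(e) & !is.na(m)
  ids <- ids[ok]; e <- e[ok]; m <- m[ok]
  total_eco <- sum(e)
  total_med <- sum(m)
  pos <- m > 0
  r <- 100 * (e[pos] - m[pos]) / m[pos]
  per_unit <- data.frame(analysis_id = ids[pos], eco = e[pos], med = m[pos],
                         rel_diff_pct = r, stringsAsFactors = FALSE)
  q <- stats::quantile(r, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  qa <- stats::quantile(abs(r), c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(
    per_unit = per_unit,
    median_pct = q[2], iqr_pct = c(q1 = q[1], q3 = q[3]),
    median_abs_pct = qa[2], iqr_abs_pct = c(q1 = qa[1], q3 = qa[3]),
    total_eco = total_eco, total_med = total_med,
    total_difference = total_eco - total_med,
    n_units = sum(pos), n_excluded = sum(!pos)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d analysis units (%d excluded, zero denominator)\n",
              x$n_units, x$n_excluded))
  cat(sprintf("  totals: eco %s vs medical %s (difference %s)\n",
              format(x$total_eco, big.mark = ","),
              format(x$total_med, big.mark = ","),
              format(x$total_difference, big.mark = ",")))
  cat(sprintf("  signed relative difference: median %.1f%% [%.1f; %.1f]\n",
              x$median_pct, x$iqr_pct[1], x$iqr_pct[2]))
  cat(sprintf("  absolute relative difference: median %.1f%% [%.1f; %.1f]\n",
              x$median_abs_pct, x$iqr_abs_pct[1], x$iqr_abs_pct[2]))
  invisible(x)
}

#' Select variables common to both databases
#'
#' Intersects the semantic tags declared in the two variable-metadata lists
#' (entry `tag`, falling back to the variable name) and ranks candidates by
#' completeness: the smaller of the two tables' fractions of units carrying a
#' value.
#'
#' @param eco_meta,med_meta named `var_meta` lists (optionally with `tag`).
#' @param eco_tab,med_tab optional [aggregated_table]s used to measure
#'   completeness; without them all candidates rank equally.
#' @return data.frame `variable_eco`, `variable_med`, `tag`, `completeness`,
#'   sorted by decreasing completeness; empty (with a warning) when the
#'   databases share no tag.
#' @export
select_common_variables <- function(eco_meta, med_meta,
                                    eco_tab = NULL, med_tab = NULL) {
  tag_of <- function(meta) {
    vapply(names(meta), function(v) {
      t <- meta[[v]]$tag
      if (is.null(t)) v else t
    }, character(1))
  }
  te <- tag_of(eco_meta)
  tm <- tag_of(med_meta)
  shared <- intersect(te, tm)
  if (length(shared) == 0L) {
    warning("no variable shared by the two databases; validation skipped")
    return(data.frame(variable_eco = character(0), variable_med = character(0),
                      tag = character(0), completeness = numeric(0)))
  }
  completeness <- function(tab, v) {
    if (is.null(tab) || !v %in% names(tab)) return(1)
    mean(!is.na(tab[[v]]))
  }
  out <- do.call(rbind, lapply(shared, function(tg) {
    ve <- names(te)[match(tg, te)]
    vm <- names(tm)[match(tg, tm)]
    data.frame(variable_eco = ve, variable_med = vm, tag = tg,
               completeness = min(completeness(eco_tab, ve),
                                  completeness(med_tab, vm)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$completeness, out$tag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a comparison report as JSON (plus per-unit CSV)
#'
#' The per-unit CSV doubles as boxplot-ready data for the relative
#' differences.
#'
#' @param report a [compare_common_variable()] result.
#' @param path JSON output path.
#' @param per_unit_path optional CSV path for per-unit differences.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path, per_unit_path = NULL) {
  payload <- report[c("median_pct", "median_abs_pct", "total_eco", "total_med",
                      "total_difference", "n_units", "n_excluded")]
  payload$iqr_pct <- as.list(report$iqr_pct)
  payload$iqr_abs_pct <- as.list(report$iqr_abs_pct)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(per_unit_path)) {
    utils::write.csv(report$per_unit, per_unit_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
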