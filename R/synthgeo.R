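# Synthetic three-level geography generator.
#
# Emulates the structure of a real national geography: a square grid of fine
# ecological units (communes), an intermediate postal-like code level, and a
# coarse medical level, linked by two transition matrices M1 (fine -> code)
# and M2 (code -> medical). Region-growing on the grid guarantees contiguous
# units, so planted discontinuities are unambiguous ground truth. Count
# databases are paired through binomial thinning so the medical side
# undercounts the ecological side by a controlled expected fraction.

#' Parameters for the synthetic geography
#'
#' Defaults emulate, at desk scale, the shape of the French application the
#' method was designed for: fine units about 6-7 times more numerous than
#' coarse units, a small fraction of one-to-one codes (~5%, codes matching a
#' single fine unit), under 1% of fine units split across codes, a few
#' percent of coarse units sharing a fine unit (the overlap situation that
#' forces merges), about 2% planted discontinuous coarse units, and a ~6%
#' expected undercount of the medical counts.
#'
#' @param grid_n fine units per side (total `grid_n^2`); cells are 1 km
#'   squares.
#' @param n_codes number of intermediate codes.
#' @param n_medical number of coarse medical units.
#' @param frac_one_to_one fraction of codes covering exactly one fine unit.
#' @param frac_split fraction of fine units linked to a second code within
#'   the same medical unit (a split that reconverges, needing no partition).
#' @param overlap_rate fraction of medical units sharing a fine unit with
#'   another medical unit (planted in adjacent pairs; forces a merge).
#' @param fragmentation_rate fraction of medical units given one non-adjacent
#'   fine unit (planted discontinuity).
#' @param lambda_count Poisson mean of events per fine unit.
#' @param undercount expected fraction of events missing from the medical
#'   database (binomial thinning probability).
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @return a `geography_params` list, validated.
#' @export
geography_params <- function(grid_n = 20L, n_codes = 70L, n_medical = 60L,
                             frac_one_to_one = 0.05, frac_split = 0.01,
                             overlap_rate = 0.02, fragmentation_rate = 0.02,
                             lambda_count = 30, undercount = 0.06,
                             seed = 1L) {
  p <- list(grid_n = as.integer(grid_n), n_codes = as.integer(n_codes),
            n_medical = as.integer(n_medical),
            frac_one_to_one = frac_one_to_one, frac_split = frac_split,
            overlap_rate = overlap_rate, fragmentation_rate = fragmentation_rate,
            lambda_count = lambda_count, undercount = undercount,
            seed = as.integer(seed))
  if (p$grid_n < 2L) stop("grid_n must be at least 2")
  F <- p$grid_n^2
  if (p$n_codes > F) stop("infeasible params: n_codes exceeds the number of fine units")
  if (p$n_medical > p$n_codes) stop("infeasible params: n_medical exceeds n_codes")
  if (p$n_medical < 1L || p$n_codes < 1L) stop("need at least one unit per level")
  fracs <- c(p$frac_one_to_one, p$frac_split, p$overlap_rate, p$fragmentation_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (p$undercount < 0 || p$undercount >= 1) stop("undercount must lie in [0, 1)")
  if (p$lambda_count < 0) stop("lambda_count must be non-negative")
  structure(p, class = "geography_params")
}

grid_neighbors <- function(i, n) {
  r <- (i - 1L) %/% n
  c <- (i - 1L) %% n
  out <- integer(0)
  if (c > 0L) out <- c(out, i - 1L)
  if (c < n - 1L) out <- c(out, i + 1L)
  if (r > 0L) out <- c(out, i - n)
  if (r < n - 1L) out <- c(out, i + n)
  out
}

# random region growing: partition 1..n_items into n_regions contiguous
# regions given an adjacency list; regions in `frozen` keep exactly one item
grow_regions <- function(n_items, n_regions, adj, frozen = integer(0)) {
  assign <- rep(NA_integer_, n_items)
  seeds <- sample.int(n_items, n_regions)
  assign[seeds] <- seq_len(n_regions)
  growable <- setdiff(seq_len(n_regions), frozen)
  while (anyNA(assign)) {
    un <- which(is.na(assign))
    cand <- un[vapply(un, function(i) {
      nb <- assign[adj[[i]]]
      any(!is.na(nb) & nb %in% growable)
    }, logical(1))]
    if (length(cand) == 0L) {
      # trapped next to frozen regions only: let frozen regions grow after all
      cand <- un[vapply(un, function(i) any(!is.na(assign[adj[[i]]])), logical(1))]
      growable <- seq_len(n_regions)
      if (length(cand) == 0L) stop("region growing stalled on a disconnected graph")
    }
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    nb <- assign[adj[[i]]]
    nb <- nb[!is.na(nb) & nb %in% growable]
    assign[i] <- if (length(nb) == 1L) nb else sample(nb, 1L)
  }
  assign
}

cell_square <- function(i, n) {
  r <- (i - 1L) %/% n
  c <- (i - 1L) %% n
  list(list(cbind(c(c, c + 1, c + 1, c), c(r, r, r + 1, r + 1))))
}

flood_connected <- function(cells, n) {
  if (length(cells) <= 1L) return(TRUE)
  inset <- logical(n * n)
  inset[cells] <- TRUE
  seen <- logical(n * n)
  stack <- cells[1]
  seen[cells[1]] <- TRUE
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (j in grid_neighbors(i, n)) {
      if (inset[j] && !seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
    }
  }
  all(seen[cells])
}

#' Generate a synthetic three-level geography
#'
#' Builds the two transition matrices, the fine and medical geometries and
#' the ground truth (analysis partition, eco assignment, planted fragmented
#' units). Deterministic given `params$seed`. All four cardinality patterns
#' are realized when the corresponding fractions are positive: region growing
#' gives many-to-one links, frozen singleton codes give one-to-one, split
#' fine units give one-to-many, and overlap planting gives the shared-unit
#' situation that forces merges.
#'
#' @param params a [geography_params] object.
#' @return list with `M1`, `M2` ([transition_matrix]), `fine_geoms`,
#'   `medical_geoms` ([geom_table]), `truth` (list: `analysis_units`,
#'   `eco_to_analysis`, `fragmented_medical`, `overlap_pairs`), `params`, and
#'   the raw assignments `cell_code`, `code_medical`.
#' @export
generate_geography <- function(params) {
  stopifnot(inherits(params, "geography_params"))
  set.seed(params$seed)
  n <- params$grid_n
  F <- n * n
  cell_ids <- sprintf("e%04d", seq_len(F))
  code_ids <- sprintf("z%03d", seq_len(params$n_codes))
  med_ids <- sprintf("m%03d", seq_len(params$n_medical))
  adj <- lapply(seq_len(F), grid_neighbors, n = n)

  n_one <- round(params$frac_one_to_one * params$n_codes)
  cell_code <- grow_regions(F, params$n_codes, adj,
                            frozen = if (n_one > 0L) seq_len(n_one) else integer(0))

  # code adjacency from cell adjacency
  code_adj <- lapply(seq_len(params$n_codes), function(z) integer(0))
  for (i in seq_len(F)) {
    for (j in adj[[i]]) {
      if (cell_code[i] != cell_code[j]) {
        code_adj[[cell_code[i]]] <- c(code_adj[[cell_code[i]]], cell_code[j])
      }
    }
  }
  code_adj <- lapply(code_adj, unique)
  code_medical <- grow_regions(params$n_codes, params$n_medical, code_adj)
  cell_medical <- code_medical[cell_code]

  # ---- plant fragmentation: move one distant cell into some medical units
  n_frag <- round(params$fragmentation_rate * params$n_medical)
  fragmented <- integer(0)
  if (n_frag > 0L) {
    targets <- sample.int(params$n_medical, n_frag)
    for (tm in targets) {
      t_cells <- which(cell_medical == tm)
      cand <- setdiff(seq_len(F), t_cells)
      cand <- cand[vapply(cand, function(i) {
        !any(adj[[i]] %in% t_cells)
      }, logical(1))]
      cand <- cand[sample.int(length(cand))]
      moved <- FALSE
      for (i in cand) {
        donor_med <- cell_medical[i]
        donor_code <- cell_code[i]
        if (donor_med %in% c(tm, fragmented)) next
        if (sum(cell_code == donor_code) < 2L) next
        rest <- setdiff(which(cell_medical == donor_med), i)
        if (length(rest) == 0L || !flood_connected(rest, n)) next
        t_codes <- which(code_medical == tm)
        cell_code[i] <- if (length(t_codes) == 1L) t_codes else sample(t_codes, 1L)
        cell_medical[i] <- tm
        fragmented <- c(fragmented, tm)
        moved <- TRUE
        break
      }
      if (!moved) warning(sprintf("could not plant fragmentation for unit %s",
                                  med_ids[tm]))
    }
  }

  extra_links <- list()  # extra (cell, code) links beyond the base assignment

  # ---- split fine units across codes inside one medical unit (reconverging)
  n_split <- round(params$frac_split * F)
  if (n_split > 0L) {
    cand <- sample.int(F)
    planted <- 0L
    for (i in cand) {
      if (planted >= n_split) break
      nb <- adj[[i]]
      opts <- unique(cell_code[nb])
      opts <- opts[opts != cell_code[i] & code_medical[opts] == cell_medical[i]]
      if (length(opts) == 0L) next
      z <- if (length(opts) == 1L) opts else sample(opts, 1L)
      extra_links[[length(extra_links) + 1L]] <- c(i, z)
      planted <- planted + 1L
    }
  }

  # ---- plant overlaps: adjacent pairs of medical units sharing one cell
  n_share <- round(params$overlap_rate * params$n_medical)
  n_pairs <- ceiling(n_share / 2)
  overlap_pairs <- list()
  if (n_pairs > 0L) {
    involved <- logical(params$n_medical)
    order_m <- sample.int(params$n_medical)
    for (a in order_m) {
      if (length(overlap_pairs) >= n_pairs) break
      if (involved[a]) next
      a_cells <- which(cell_medical == a)
      # border cells of neighbouring units that touch unit a
      touch <- unique(unlist(lapply(a_cells, function(i) adj[[i]])))
      touch <- touch[cell_medical[touch] != a]
      touch <- touch[!involved[cell_medical[touch]]]
      if (length(touch) == 0L) next
      i <- if (length(touch) == 1L) touch else sample(touch, 1L)
      b <- cell_medical[i]
      # link the shared cell to the adjacent code of unit a
      nb_codes <- unique(cell_code[adj[[i]]])
      nb_codes <- nb_codes[code_medical[nb_codes] == a]
      z <- if (length(nb_codes) == 1L) nb_codes else sample(nb_codes, 1L)
      extra_links[[length(extra_links) + 1L]] <- c(i, z)
      overlap_pairs[[length(overlap_pairs) + 1L]] <- sort(c(a, b))
      involved[c(a, b)] <- TRUE
    }
  }

  # ---- assemble matrices
  m1_src <- cell_ids
  m1_tgt <- code_ids[cell_code]
  if (length(extra_links)) {
    m1_src <- c(m1_src, cell_ids[vapply(extra_links, `[`, integer(1), 1L)])
    m1_tgt <- c(m1_tgt, code_ids[vapply(extra_links, `[`, integer(1), 2L)])
  }
  M1 <- transition_matrix(m1_src, m1_tgt, k = 1L)
  M2 <- transition_matrix(code_ids, med_ids[code_medical], k = 2L)

  # ---- ground truth partition via union-find over planted share pairs
  parent <- seq_len(params$n_medical)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (pr in overlap_pairs) parent[find(pr[1])] <- find(pr[2])
  root <- vapply(seq_len(params$n_medical), find, integer(1))
  groups <- split(med_ids, root)
  unit_names <- vapply(groups, function(g) paste(sort(g), collapse = "+"), character(1))
  analysis_units <- stats::setNames(lapply(groups, sort), unit_names)
  med_to_analysis <- stats::setNames(rep(unit_names, lengths(groups)), unlist(groups))
  eco_to_analysis <- stats::setNames(unname(med_to_analysis[med_ids[cell_medical]]),
                                     cell_ids)

  # ---- geometries
  fine_geoms <- geom_table(stats::setNames(lapply(seq_len(F), cell_square, n = n),
                                           cell_ids))
  med_members <- split(seq_len(F), cell_medical)
  shared_cells <- if (length(overlap_pairs)) {
    vapply(extra_links[seq.int(length(extra_links) - length(overlap_pairs) + 1L,
                               length(extra_links))], `[`, integer(1), 1L)
  } else integer(0)
  medical_geoms <- geom_table(stats::setNames(lapply(seq_len(params$n_medical), function(mi) {
    cells <- med_members[[as.character(mi)]]
    # overlap-shared cells belong to both units' territories
    if (length(shared_cells)) {
      extra <- vapply(extra_links, `[`, integer(1), 2L)
      owners <- code_medical[extra]
      add <- vapply(extra_links, `[`, integer(1), 1L)[owners == mi]
      cells <- unique(c(cells, intersect(add, shared_cells)))
    }
    union_parts(lapply(cells, function(i) cell_square(i, n)[[1]]))
  }), med_ids))

  list(M1 = M1, M2 = M2,
       fine_geoms = fine_geoms, medical_geoms = medical_geoms,
       truth = list(analysis_units = analysis_units,
                    eco_to_analysis = eco_to_analysis,
                    fragmented_medical = sort(med_ids[unique(fragmented)]),
                    overlap_pairs = lapply(overlap_pairs, function(pr) med_ids[pr])),
       params = params,
       cell_code = stats::setNames(code_ids[cell_code], cell_ids),
       code_medical = stats::setNames(med_ids[code_medical], code_ids))
}

#' Generate paired count databases for a synthetic geography
#'
#' Fine-unit event counts are Poisson(`lambda_count`); the medical database
#' records, per coarse unit, the sum of its member cells' counts after
#' binomial thinning with keep probability `1 - undercount`. Thinning keeps
#' counts integer and non-negative, and events are counted once: each cell's
#' events go to the medical unit of its primary code. Deterministic given the
#' params seed (a fixed offset of the geography seed, so geography and counts
#' draw from independent streams).
#'
#' @param geography result of [generate_geography()].
#' @param params the same [geography_params].
#' @return list with `eco` (fine-level [aggregated_table], variable
#'   `births`), `med` (medical-level table, variable `births`), and
#'   `true_counts` (named vector of fine-unit counts).
#' @export
generate_counts <- function(geography, params = geography$params) {
  set.seed(params$seed + 1000003L)
  cell_ids <- names(geography$cell_code)
  F <- length(cell_ids)
  counts <- stats::rpois(F, params$lambda_count)
  kept <- stats::rbinom(F, counts, 1 - params$undercount)
  med_of_cell <- geography$code_medical[geography$cell_code]
  med_counts <- tapply(kept, med_of_cell, sum)
  med_ids <- names(geography$medical_geoms$geoms)
  med_vec <- stats::setNames(rep(0L, length(med_ids)), med_ids)
  med_vec[names(med_counts)] <- as.integer(med_counts)
  meta <- list(births = list(kind = "count", tag = "births"))
  list(eco = aggregated_table(data.frame(id = cell_ids, births = counts,
                                         stringsAsFactors = FALSE),
                              var_meta = meta, level = 1L),
       med = aggregated_table(data.frame(id = med_ids, births = as.integer(med_vec),
                                         stringsAsFactors = FALSE),
                              var_meta = meta, level = 3L),
       true_counts = stats::setNames(counts, cell_ids))
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits `M1.csv`, `M2.csv`, `eco.csv`, `med.csv`, `var_meta.yaml`,
#' `fine.geojson`, `medical.geojson` and `truth.json`.
#'
#' @param geography result of [generate_geography()].
#' @param counts result of [generate_counts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(geography, counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transition_matrix(geography$M1, file.path(dir, "M1.csv"))
  write_transition_matrix(geography$M2, file.path(dir, "M2.csv"))
  write_aggregated_table(counts$eco, file.path(dir, "eco.csv"))
  write_aggregated_table(counts$med, file.path(dir, "med.csv"))
  yaml::write_yaml(list(births = list(kind = "count", tag = "births")),
                   file.path(dir, "var_meta.yaml"))
  write_geometries(geography$fine_geoms, file.path(dir, "fine.geojson"))
  write_geometries(geography$medical_geoms, file.path(dir, "medical.geojson"))
  jsonlite::write_json(list(
    analysis_units = geography$truth$analysis_units,
    eco_to_analysis = as.list(geography$truth$eco_to_analysis),
    fragmented_medical = geography$truth$fragmented_medical
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
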