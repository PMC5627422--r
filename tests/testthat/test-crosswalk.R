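# Mapping-table construction: direction, situations, composition, merging.

test_that("the larger-median database seeds the analysis units", {
  # medians reported for the French application: 70 km^2 vs 10.8 km^2
  med <- c(60, 70, 80)
  eco <- c(10, 10.8, 12)
  d <- choose_direction(med, eco)
  expect_identical(d$base, "medical")
  expect_equal(d$median_med, 70)
  expect_equal(d$median_eco, 10.8)

  expect_error(choose_direction(c(1, 2, 3), c(3, 2, 1)), "ambiguous direction")

  set.seed(11)
  a <- stats::rlnorm(200, 3, 1)
  b <- stats::rlnorm(200, 1, 1)
  d2 <- choose_direction(a, b)
  expect_equal(d2$median_med, oracle_median(a))
  expect_equal(d2$median_eco, oracle_median(b))
  expect_identical(d2$base, if (oracle_median(a) > oracle_median(b)) "medical" else "eco")
})

test_that("equivalence situations are the four cardinality patterns", {
  m <- transition_matrix(c("e1"), c("z1"))
  expect_identical(classify_components(m)$situation, "one_to_one")

  m <- transition_matrix(c("e1", "e2"), c("z1", "z1"))
  cc <- classify_components(m)
  expect_identical(cc$situation, "many_to_one")
  expect_equal(cc$n_links, 2L)

  m <- transition_matrix(c("e1", "e1"), c("z1", "z2"))
  expect_identical(classify_components(m)$situation, "one_to_many")

  m <- transition_matrix(c("e1", "e1", "e2"), c("z1", "z2", "z2"))
  expect_identical(classify_components(m)$situation, "many_to_many")
})

test_that("component labelling matches an exhaustive flood-fill oracle", {
  # all non-empty bipartite graphs on 3 sources x 3 targets, via random draws
  # over the full edge set plus every single-edge graph
  srcs <- paste0("e", 1:3)
  tgts <- paste0("z", 1:3)
  edges <- expand.grid(s = srcs, t = tgts, stringsAsFactors = FALSE)
  cases <- c(lapply(seq_len(nrow(edges)), function(i) edges[i, , drop = FALSE]),
             local({
               set.seed(4)
               lapply(1:40, function(i) edges[sample(9, sample(2:9, 1)), ])
             }))
  for (case in cases) {
    m <- transition_matrix(case$s, case$t)
    cc <- classify_components(m)
    lab <- oracle_bipartite_components(m$source_id, m$target_id)
    expect_equal(nrow(cc), length(unique(lab)))
    # links partition across components
    expect_equal(sum(cc$n_links), nrow(m))
    # situations agree with oracle component cardinalities
    for (i in seq_len(nrow(cc))) {
      s <- cc$sources[[i]]; t <- cc$targets[[i]]
      expect_identical(unique(lab[paste0("S:", s)]), unname(lab[paste0("S:", s[1])]))
      want <- if (length(s) == 1 && length(t) == 1) "one_to_one"
      else if (length(t) == 1) "many_to_one"
      else if (length(s) == 1) "one_to_many"
      else "many_to_many"
      expect_identical(cc$situation[i], want)
    }
  }
})

test_that("composition equals brute-force path enumeration", {
  m1 <- transition_matrix(c("e1", "e2"), c("z1", "z1"), k = 1)
  m2 <- transition_matrix("z1", "m1", k = 2)
  g <- compose_matrices(list(m1, m2))
  expect_identical(g$eco_id, c("e1", "e2"))
  expect_identical(g$medical_id, c("m1", "m1"))

  # p = 1: the linkage is the matrix itself
  g1 <- compose_matrices(list(transition_matrix("e1", "m1")))
  expect_identical(g1$eco_id, "e1")
  expect_identical(g1$medical_id, "m1")

  # random 3-level chains vs path-existence oracle
  set.seed(1)
  for (rep in 1:5) {
    n <- 50
    l1 <- sprintf("a%02d", 1:n); l2 <- sprintf("b%02d", 1:n); l3 <- sprintf("c%02d", 1:n)
    pick <- function(src, tgt) {
      sel <- which(stats::runif(n * n) < 0.05)
      data.frame(source_id = src[(sel - 1) %% n + 1],
                 target_id = tgt[(sel - 1) %/% n + 1], stringsAsFactors = FALSE)
    }
    d1 <- pick(l1, l2); d2 <- pick(l2, l3)
    if (nrow(d1) == 0 || nrow(d2) == 0) next
    m1 <- transition_matrix(d1$source_id, d1$target_id, k = 1)
    m2 <- transition_matrix(d2$source_id, d2$target_id, k = 2)
    got <- suppressWarnings(compose_matrices(list(m1, m2)))
    want <- oracle_compose(list(d1, d2))
    expect_identical(got$eco_id, want$source_id)
    expect_identical(got$medical_id, want$target_id)
  }
})

test_that("chain breaks and dangling IDs are surfaced, not swallowed", {
  m1 <- transition_matrix("e1", "z1", k = 1)
  m3 <- transition_matrix("z1", "m1", k = 3)
  expect_error(compose_matrices(list(m1, m3)), "chain break")

  m2 <- transition_matrix(c("z1", "zX"), c("m1", "m2"), k = 2)
  m1b <- transition_matrix(c("e1", "e2"), c("z1", "zGone"), k = 1)
  expect_warning(g <- compose_matrices(list(m1b, m2)), "dangling")
  d <- attr(g, "dangling")$M2
  expect_identical(d$targets_without_source, "zGone")
  expect_identical(d$sources_without_target, "zX")
  # dangling ids are excluded from the linkage
  expect_identical(g$eco_id, "e1")
})

test_that("overlap merging matches a union-find oracle", {
  g <- merge_overlapping(data.frame(eco_id = c("e1", "e1"), medical_id = c("m1", "m2")))
  expect_identical(names(attr(g, "analysis_units")), "m1+m2")

  g2 <- merge_overlapping(data.frame(eco_id = c("e1", "e2"), medical_id = c("m1", "m2")))
  expect_equal(length(attr(g2, "analysis_units")), 2L)

  for (seed in 1:10) {
    set.seed(seed)
    n_eco <- 100; n_med <- 30
    sel <- which(stats::runif(n_eco * n_med) < 0.03)
    df <- data.frame(eco_id = sprintf("e%03d", (sel - 1) %% n_eco + 1),
                     medical_id = sprintf("m%02d", (sel - 1) %/% n_eco + 1),
                     stringsAsFactors = FALSE)
    if (nrow(df) == 0) next
    mt <- merge_overlapping(df)
    expect_same_partition(attr(mt, "analysis_units"),
                          oracle_shared_partition(df$eco_id, df$medical_id))
  }
})

test_that("every eco id maps to exactly one analysis unit; merge is idempotent and monotone", {
  set.seed(21)
  sel <- which(stats::runif(100 * 30) < 0.04)
  df <- data.frame(eco_id = sprintf("e%03d", (sel - 1) %% 100 + 1),
                   medical_id = sprintf("m%02d", (sel - 1) %/% 100 + 1),
                   stringsAsFactors = FALSE)
  mt <- merge_overlapping(df)
  # functionality: eco -> analysis is a total function on linked eco ids
  eco_units <- tapply(mt$analysis_id, mt$eco_id, function(x) length(unique(x)))
  expect_true(all(eco_units == 1L))

  # idempotence: merging the merged relation changes nothing
  df2 <- data.frame(eco_id = mt$eco_id, medical_id = mt$analysis_id)
  mt2 <- merge_overlapping(df2)
  expect_equal(length(attr(mt2, "analysis_units")), length(attr(mt, "analysis_units")))

  # monotonicity: adding links never increases the number of analysis units
  n_prev <- length(attr(mt, "analysis_units"))
  for (i in 1:20) {
    extra <- data.frame(eco_id = sprintf("e%03d", sample(100, 1)),
                        medical_id = sprintf("m%02d", sample(30, 1)))
    df <- unique(rbind(df, extra))
    n_now <- length(attr(merge_overlapping(df), "analysis_units"))
    # new medical ids can add units; restrict to the merging direction
    if (extra$medical_id %in% df$medical_id[-nrow(df)]) {
      expect_lte(n_now, n_prev + 1L)
    }
    n_prev <- n_now
  }
})

test_that("build_mapping_table orchestrates and reports a situation census", {
  # four communes through two zips that both feed one medical unit
  m1 <- transition_matrix(c("e1", "e2", "e3", "e4"), c("z1", "z1", "z2", "z2"), k = 1)
  m2 <- transition_matrix(c("z1", "z2"), c("m1", "m1"), k = 2)
  mt <- build_mapping_table(list(m1, m2))
  units <- attr(mt, "analysis_units")
  expect_equal(length(units), 1L)
  expect_equal(sort(unique(mt$eco_id)), c("e1", "e2", "e3", "e4"))
  census <- attr(mt, "census")
  expect_equal(census$M1$many_to_one$links, 4L)
  expect_equal(census$M1$many_to_one$pct, 100)
  expect_equal(census$n_analysis_units, 1L)

  # no overlap: analysis units = medical units
  p <- geography_params(overlap_rate = 0, frac_split = 0, seed = 3)
  g <- generate_geography(p)
  mt2 <- build_mapping_table(list(g$M1, g$M2))
  expect_equal(length(attr(mt2, "analysis_units")), p$n_medical)
  expect_equal(attr(mt2, "census")$overlap_merges$analysis_units_created, 0L)

  # ground-truth partition recovered on a mixed geography
  p3 <- geography_params(seed = 42)
  g3 <- generate_geography(p3)
  mt3 <- build_mapping_table(list(g3$M1, g3$M2))
  expect_same_partition(attr(mt3, "analysis_units"), g3$truth$analysis_units)
})

test_that("mapping tables round-trip through CSV with attributes rebuilt", {
  p <- geography_params(seed = 5)
  g <- generate_geography(p)
  mt <- build_mapping_table(list(g$M1, g$M2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_mapping_table(mt, f)
  mt2 <- read_mapping_table(f)
  expect_same_partition(attr(mt2, "analysis_units"), attr(mt, "analysis_units"))
  expect_identical(attr(mt2, "eco_to_analysis")[order(names(attr(mt2, "eco_to_analysis")))],
                   attr(mt, "eco_to_analysis")[order(names(attr(mt, "eco_to_analysis")))])
})
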