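# Spatial validation: dissolve, fragmentation, centroids, decline index.

gt1 <- function(parts) geom_table(list(u = parts))

test_that("dissolve merges edge-adjacent members and keeps disjoint ones apart", {
  mapping <- merge_overlapping(data.frame(eco_id = c("x", "y"),
                                          medical_id = c("m1", "m1")))
  # two unit squares sharing an edge -> one part, area 2
  geoms <- geom_table(list(x = list(square_part(0, 0)),
                           y = list(square_part(1, 0))))
  dg <- dissolve(geoms, mapping)
  expect_equal(length(dg$geoms[[1]]), 1L)
  expect_equal(unname(dg$areas), 2)

  # two disjoint squares -> two parts, area still additive
  geoms2 <- geom_table(list(x = list(square_part(0, 0)),
                            y = list(square_part(5, 0))))
  dg2 <- dissolve(geoms2, mapping)
  expect_equal(length(dg2$geoms[[1]]), 2L)
  expect_equal(unname(dg2$areas), 2)

  # corner-touching squares stay separate parts (no positive shared boundary)
  geoms3 <- geom_table(list(x = list(square_part(0, 0)),
                            y = list(square_part(1, 1))))
  dg3 <- dissolve(geoms3, mapping)
  expect_equal(length(dg3$geoms[[1]]), 2L)

  expect_error(dissolve(geom_table(list(zz = list(square_part(0, 0)))), mapping),
               "no member geometries")
})

test_that("dissolved areas equal the sum of member areas on random grid assignments", {
  set.seed(3)
  for (rep in 1:50) {
    n <- 6
    cells <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
    ids <- sprintf("c%02d", seq_len(nrow(cells)))
    unit <- sprintf("m%d", sample(4, nrow(cells), replace = TRUE))
    geoms <- geom_table(stats::setNames(
      lapply(seq_len(nrow(cells)), function(i) list(square_part(cells$x[i], cells$y[i]))),
      ids))
    mapping <- merge_overlapping(data.frame(eco_id = ids, medical_id = unit))
    dg <- dissolve(geoms, mapping)
    for (aid in names(dg$geoms)) {
      members <- names(which(attr(mapping, "eco_to_analysis") == aid))
      expect_equal(unname(dg$areas[aid]), length(members), tolerance = 1e-9)
    }
    expect_equal(sum(dg$areas), nrow(cells), tolerance = 1e-9)
  }
})

test_that("single-member dissolve returns the input geometry", {
  mapping <- merge_overlapping(data.frame(eco_id = c("x", "y"),
                                          medical_id = c("m1", "m2")))
  geoms <- geom_table(list(x = list(square_part(0, 0)),
                           y = list(square_part(7, 3, side = 2))))
  dg <- dissolve(geoms, mapping)
  expect_equal(unname(dg$areas[order(names(dg$areas))]), c(1, 4), tolerance = 1e-9)
})

test_that("fragmentation counts discontinuous units with rook contiguity", {
  # all single-part units: 0%
  g <- geom_table(list(a = list(square_part(0, 0)), b = list(square_part(5, 0))))
  fr <- fragmentation_index(g)
  expect_equal(fr$pct, 0)

  # glued edge-wise vs corner-wise, against a grid flood-fill oracle
  set.seed(6)
  for (rep in 1:10) {
    n_sq <- sample(2:6, 1)
    cells <- unique(cbind(sample(0:4, n_sq, replace = TRUE),
                          sample(0:4, n_sq, replace = TRUE)))
    mp <- lapply(seq_len(nrow(cells)), function(i) square_part(cells[i, 1], cells[i, 2]))
    got <- fragmentation_index(geom_table(list(u = mp)))
    want_parts <- oracle_grid_components(cells)
    expect_identical(got$n_fragmented, as.integer(want_parts > 1))
  }

  # a diagonal (corner-touching) pair is fragmented; an edge pair is not
  frag <- geom_table(list(u = list(square_part(0, 0), square_part(1, 1))))
  expect_equal(fragmentation_index(frag)$n_fragmented, 1L)
  whole <- geom_table(list(u = list(square_part(0, 0), square_part(1, 0))))
  expect_equal(fragmentation_index(whole)$n_fragmented, 0L)
})

test_that("fragmentation is invariant under translation, rotation and scaling", {
  mp <- list(square_part(0, 0), square_part(3, 2))
  transform <- function(mp, f) lapply(mp, function(part) lapply(part, f))
  variants <- list(
    mp,
    transform(mp, function(r) r + 10),
    transform(mp, function(r) r %*% matrix(c(cos(0.7), sin(0.7), -sin(0.7), cos(0.7)), 2)),
    transform(mp, function(r) r * 0.013)
  )
  for (v in variants) {
    expect_equal(fragmentation_index(geom_table(list(u = v)))$n_fragmented, 1L)
  }
})

test_that("planted fragmentation is recovered exactly on the synthetic geography", {
  p <- geography_params(fragmentation_rate = 0.1, seed = 23)
  g <- generate_geography(p)
  fr <- fragmentation_index(g$medical_geoms)
  expect_identical(fr$fragmented_ids, g$truth$fragmented_medical)
  expect_equal(fr$n_fragmented, length(g$truth$fragmented_medical))
})

test_that("centroids of fragmented units can fall outside; containment flags them", {
  # convex square: centroid inside
  one <- geom_table(list(u = list(square_part(0, 0))))
  expect_equal(centroid_containment(one)$n_outside, 0L)

  # two distant squares: the centroid sits midway, in the gap
  two <- geom_table(list(u = list(square_part(0, 0), square_part(10, 0))))
  cc <- centroid_containment(two)
  expect_equal(cc$n_outside, 1L)
  expect_equal(arealink:::multipolygon_centroid(two$geoms$u), c(5.5, 0.5))

  # random multi-square units vs a winding-number oracle
  set.seed(31)
  for (rep in 1:100) {
    k <- sample(1:3, 1)
    xs <- sample(seq(0, 40, by = 3), k)
    mp <- lapply(xs, function(x) square_part(x, 0))
    cen <- arealink:::multipolygon_centroid(mp)
    got <- arealink:::point_in_multipolygon(cen, mp)
    on_boundary <- any(vapply(mp, function(part) {
      arealink:::point_on_ring(cen, part[[1]])
    }, logical(1)))
    if (!on_boundary) {
      expect_identical(got, oracle_point_in_mp_winding(cen, mp))
    }
  }
})

test_that("the decline index is the ratio of medians", {
  # application medians: 70 km^2 (analysis) over 10.8 km^2 (finest unit)
  expect_equal(round(resolution_decline_index(70, 10.8), 1), 6.5)
  expect_equal(resolution_decline_index(4.2, 4.2), 1.0)
  set.seed(37)
  a <- stats::rlnorm(151, 2, 0.8)
  b <- stats::rlnorm(151, 1, 0.8)
  expect_equal(resolution_decline_index(stats::median(a), stats::median(b)),
               oracle_median(a) / oracle_median(b))
  expect_error(resolution_decline_index(0, 1), "positive")
})

test_that("the spatial report assembles indices and flags finer scales", {
  p <- geography_params(seed = 41)
  g <- generate_geography(p)
  mt <- build_mapping_table(list(g$M1, g$M2))
  dg <- dissolve(g$fine_geoms, mt)
  rep <- spatial_validation(dg, initial_median_km2 = stats::median(g$fine_geoms$areas),
                            references = list(canton = list(median_area_km2 = 146.2)))
  expect_s3_class(rep, "spatial_report")
  expect_gte(rep$fragmentation_pct, 0)
  expect_lte(rep$fragmentation_pct, 100)
  expect_equal(rep$fragmentation_pct, 100 * rep$n_fragmented / rep$n_units)
  # decline of a level against itself is exactly 1; fine cells are 1 km^2
  expect_equal(rep$decline_indices$analysis$surface_ratio, rep$median_area_km2)
  expect_true(rep$decline_indices$canton$analysis_is_finer)
})
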