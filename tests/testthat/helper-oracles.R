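# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid igraph and the package's geometry code paths.

# connected components of a bipartite link set by label propagation
oracle_bipartite_components <- function(source_id, target_id) {
  nodes <- c(paste0("S:", unique(source_id)), paste0("T:", unique(target_id)))
  lab <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_along(source_id)) {
      a <- paste0("S:", source_id[i]); b <- paste0("T:", target_id[i])
      m <- min(lab[a], lab[b])
      if (lab[a] != m || lab[b] != m) { lab[a] <- m; lab[b] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

# partition of medical ids into groups sharing >= 1 eco id, by union-find
oracle_shared_partition <- function(eco_id, medical_id) {
  med <- sort(unique(medical_id))
  parent <- stats::setNames(seq_along(med), med)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  by_eco <- split(medical_id, eco_id)
  for (ms in by_eco) {
    ms <- unique(ms)
    if (length(ms) > 1L) {
      for (k in 2:length(ms)) {
        ra <- find(match(ms[1], med)); rb <- find(match(ms[k], med))
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_along(med), find, numeric(1))
  unname(lapply(split(med, roots), sort))
}

canonical_partition <- function(groups) {
  groups <- unname(lapply(groups, function(g) sort(unname(g))))
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

# all-pairs path existence through a chain of link data.frames
oracle_compose <- function(mats) {
  reach <- unique(mats[[1]][, c("source_id", "target_id")])
  if (length(mats) > 1L) {
    for (k in 2:length(mats)) {
      nxt <- mats[[k]]
      out <- list()
      for (i in seq_len(nrow(reach))) {
        hit <- nxt$target_id[nxt$source_id == reach$target_id[i]]
        if (length(hit)) out[[length(out) + 1L]] <-
            data.frame(source_id = reach$source_id[i], target_id = hit,
                       stringsAsFactors = FALSE)
      }
      reach <- unique(do.call(rbind, out))
    }
  }
  reach <- reach[order(reach$source_id, reach$target_id), ]
  rownames(reach) <- NULL
  reach
}

# sort-based median (midpoint of central pair for even n)
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# type-7 quantile from first principles
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# winding-number point-in-polygon (boundary not handled; callers avoid it)
oracle_point_in_ring_winding <- function(p, ring) {
  n <- nrow(ring)
  wn <- 0
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[if (i == n) 1 else i + 1, ]
    is_left <- (b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2])
    if (a[2] <= p[2]) {
      if (b[2] > p[2] && is_left > 0) wn <- wn + 1
    } else {
      if (b[2] <= p[2] && is_left < 0) wn <- wn - 1
    }
  }
  wn != 0
}

oracle_point_in_mp_winding <- function(p, mp) {
  for (part in mp) {
    if (oracle_point_in_ring_winding(p, part[[1]])) {
      in_hole <- FALSE
      if (length(part) > 1) {
        for (h in part[-1]) if (oracle_point_in_ring_winding(p, h)) in_hole <- TRUE
      }
      if (!in_hole) return(TRUE)
    }
  }
  FALSE
}

# flood fill over rook adjacency of unit grid squares given by (col, row)
# lower-left corners; returns the number of connected blocks
oracle_grid_components <- function(cells) {
  n <- nrow(cells)
  if (n == 0) return(0L)
  comp <- rep(NA_integer_, n)
  nxt <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    nxt <- nxt + 1L
    stack <- s
    comp[s] <- nxt
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (j in seq_len(n)) {
        if (is.na(comp[j]) &&
            abs(cells[i, 1] - cells[j, 1]) + abs(cells[i, 2] - cells[j, 2]) == 1) {
          comp[j] <- nxt
          stack <- c(stack, j)
        }
      }
    }
  }
  nxt
}

# a unit grid square multipolygon part from its lower-left corner
square_part <- function(x, y, side = 1) {
  list(cbind(c(x, x + side, x + side, x), c(y, y, y + side, y + side)))
}

expect_same_partition <- function(got, want) {
  expect_identical(canonical_partition(got), canonical_partition(want))
}
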