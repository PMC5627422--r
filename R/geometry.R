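# Planar polygon primitives.
#
# Geometries are stored as plain R lists: a multipolygon is a list of parts,
# each part is a list of rings, each ring an n x 2 numeric matrix of vertices
# (not closed: the first vertex is not repeated). Ring 1 of a part is the
# outer boundary; further rings are holes. Coordinates are assumed to be in a
# planar projected CRS with km units unless stated otherwise, so shoelace
# areas are km^2 directly.

# ---- rings ----------------------------------------------------------------

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# first moment of a ring (for the area centroid); signed like the area
ring_moment <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / 6
}

# force outer rings counter-clockwise and holes clockwise
orient_part <- function(part) {
  out <- part
  if (ring_signed_area(out[[1]]) < 0) out[[1]] <- out[[1]][rev(seq_len(nrow(out[[1]]))), , drop = FALSE]
  if (length(out) > 1) {
    for (i in 2:length(out)) {
      if (ring_signed_area(out[[i]]) > 0) out[[i]] <- out[[i]][rev(seq_len(nrow(out[[i]]))), , drop = FALSE]
    }
  }
  out
}

part_area <- function(part) {
  a <- abs(ring_signed_area(part[[1]]))
  if (length(part) > 1) {
    a <- a - sum(vapply(part[-1], function(h) abs(ring_signed_area(h)), numeric(1)))
  }
  a
}

#' Area of a multipolygon
#'
#' Planar (shoelace) area; hole rings are subtracted. With coordinates in km
#' the result is km^2.
#'
#' @param mp a multipolygon: list of parts, each a list of ring matrices.
#' @return numeric scalar area.
#' @keywords internal
multipolygon_area <- function(mp) {
  sum(vapply(mp, part_area, numeric(1)))
}

#' Area centroid of a multipolygon
#'
#' The area-weighted centroid of all parts, with holes subtracted. This is the
#' plain geometric centroid, which for a fragmented unit can fall outside
#' every part.
#'
#' @param mp a multipolygon.
#' @return numeric length-2 vector (x, y).
#' @keywords internal
multipolygon_centroid <- function(mp) {
  A <- 0
  M <- c(0, 0)
  for (part in mp) {
    part <- orient_part(part)
    for (ring in part) {
      A <- A + ring_signed_area(ring)
      M <- M + ring_moment(ring)
    }
  }
  if (abs(A) < .Machine$double.eps) stop("degenerate geometry: zero area")
  M / A
}

# ---- point in polygon ------------------------------------------------------

point_on_segment <- function(p, a, b, tol = 1e-9) {
  cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  if (abs(cross) > tol * max(1, abs(b[1] - a[1]) + abs(b[2] - a[2]))) return(FALSE)
  dot <- (p[1] - a[1]) * (b[1] - a[1]) + (p[2] - a[2]) * (b[2] - a[2])
  len2 <- (b[1] - a[1])^2 + (b[2] - a[2])^2
  dot >= -tol && dot <= len2 + tol
}

point_on_ring <- function(p, ring, tol = 1e-9) {
  n <- nrow(ring)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (point_on_segment(p, ring[i, ], ring[j, ], tol)) return(TRUE)
  }
  FALSE
}

# even-odd ray casting; boundary handled separately by callers
point_in_ring <- function(p, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > p[2]) != (yj > p[2])) {
      xint <- (xj - xi) * (p[2] - yi) / (yj - yi) + xi
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Point-in-multipolygon test
#'
#' Even-odd rule per part (outer ring minus holes); a point exactly on any
#' boundary counts as inside.
#'
#' @param p numeric length-2 point.
#' @param mp a multipolygon.
#' @param tol boundary snap tolerance in coordinate units.
#' @return logical scalar.
#' @keywords internal
point_in_multipolygon <- function(p, mp, tol = 1e-9) {
  for (part in mp) {
    for (ring in part) if (point_on_ring(p, ring, tol)) return(TRUE)
    if (point_in_ring(p, part[[1]])) {
      in_hole <- FALSE
      if (length(part) > 1) {
        for (h in part[-1]) if (point_in_ring(p, h)) { in_hole <- TRUE; break }
      }
      if (!in_hole) return(TRUE)
    }
  }
  FALSE
}

# ---- shared boundaries (rook contiguity) -----------------------------------

# all boundary edges of a multipolygon as a matrix [x1 y1 x2 y2]
mp_edges <- function(mp) {
  segs <- list()
  for (part in mp) {
    for (ring in part) {
      n <- nrow(ring)
      nxt <- c(2:n, 1L)
      segs[[length(segs) + 1L]] <- cbind(ring, ring[nxt, , drop = FALSE])
    }
  }
  do.call(rbind, segs)
}

# length of collinear overlap between two segments, 0 if none
segment_overlap_length <- function(a1, a2, b1, b2, tol = 1e-9) {
  d <- a2 - a1
  len <- sqrt(sum(d^2))
  if (len < tol) return(0)
  u <- d / len
  # both endpoints of b must lie on the supporting line of a
  cr1 <- u[1] * (b1[2] - a1[2]) - u[2] * (b1[1] - a1[1])
  cr2 <- u[1] * (b2[2] - a1[2]) - u[2] * (b2[1] - a1[1])
  if (abs(cr1) > tol || abs(cr2) > tol) return(0)
  t1 <- sum((b1 - a1) * u)
  t2 <- sum((b2 - a1) * u)
  lo <- max(0, min(t1, t2))
  hi <- min(len, max(t1, t2))
  max(0, hi - lo)
}

#' Do two multipolygons share a boundary of positive length?
#'
#' Rook-style contiguity: TRUE only if some pair of boundary edges overlaps
#' collinearly over a length greater than `tol`. Corner (point) contact
#' returns FALSE.
#'
#' @param mp_a,mp_b multipolygons.
#' @param tol snap tolerance in coordinate units.
#' @return logical scalar.
#' @keywords internal
shares_positive_boundary <- function(mp_a, mp_b, tol = 1e-9) {
  ea <- mp_edges(mp_a)
  eb <- mp_edges(mp_b)
  # cheap bbox reject
  if (min(ea[, c(1, 3)]) > max(eb[, c(1, 3)]) + tol ||
      max(ea[, c(1, 3)]) < min(eb[, c(1, 3)]) - tol ||
      min(ea[, c(2, 4)]) > max(eb[, c(2, 4)]) + tol ||
      max(ea[, c(2, 4)]) < min(eb[, c(2, 4)]) - tol) return(FALSE)
  for (i in seq_len(nrow(ea))) {
    a1 <- ea[i, 1:2]; a2 <- ea[i, 3:4]
    lo <- pmin(a1, a2) - tol; hi <- pmax(a1, a2) + tol
    for (j in seq_len(nrow(eb))) {
      b1 <- eb[j, 1:2]; b2 <- eb[j, 3:4]
      if (max(b1[1], b2[1]) < lo[1] || min(b1[1], b2[1]) > hi[1] ||
          max(b1[2], b2[2]) < lo[2] || min(b1[2], b2[2]) > hi[2]) next
      if (segment_overlap_length(a1, a2, b1, b2, tol) > tol) return(TRUE)
    }
  }
  FALSE
}

# rook-connected components among a list of single parts (each a polygon);
# returns integer component label per part
rook_components <- function(parts, tol = 1e-9) {
  n <- length(parts)
  if (n == 1L) return(1L)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (find(i) != find(j) &&
          shares_positive_boundary(list(parts[[i]]), list(parts[[j]]), tol)) {
        comp[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# ---- union by boundary cancellation ----------------------------------------

# Dissolve a set of parts whose shared internal edges coincide (possibly
# partially) into boundary rings: every edge is split at all vertices lying on
# it, segments appearing an even number of times are internal and cancel, the
# remaining segments are stitched into closed rings. Exact for geometries
# whose common borders are collinear (grids, administrative tilings); inputs
# that overlap with crossing edges are outside its contract.
cancel_union <- function(parts, tol = 1e-9) {
  edges <- do.call(rbind, lapply(parts, function(p) mp_edges(list(p))))
  snap <- function(x) round(x / tol) * tol
  verts <- unique(snap(rbind(edges[, 1:2, drop = FALSE], edges[, 3:4, drop = FALSE])))
  # split every edge at vertices interior to it
  split_segs <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1:2]; b <- edges[i, 3:4]
    d <- b - a
    len <- sqrt(sum(d^2))
    if (len < tol) next
    u <- d / len
    t_int <- numeric(0)
    cr <- abs(u[1] * (verts[, 2] - a[2]) - u[2] * (verts[, 1] - a[1]))
    tt <- (verts[, 1] - a[1]) * u[1] + (verts[, 2] - a[2]) * u[2]
    sel <- cr < tol & tt > tol & tt < len - tol
    t_int <- sort(unique(tt[sel]))
    ts <- c(0, t_int, len)
    pts <- cbind(a[1] + ts * u[1], a[2] + ts * u[2])
    for (s in seq_len(nrow(pts) - 1L)) {
      split_segs[[length(split_segs) + 1L]] <- c(pts[s, ], pts[s + 1L, ])
    }
  }
  segm <- do.call(rbind, split_segs)
  segm <- snap(segm)
  # canonical undirected key
  flip <- segm[, 1] > segm[, 3] | (segm[, 1] == segm[, 3] & segm[, 2] > segm[, 4])
  canon <- segm
  canon[flip, ] <- segm[flip, c(3, 4, 1, 2)]
  key <- paste(canon[, 1], canon[, 2], canon[, 3], canon[, 4], sep = "|")
  cnt <- table(key)
  keep_keys <- names(cnt)[as.integer(cnt) %% 2L == 1L]
  keep <- canon[match(keep_keys, key), , drop = FALSE]
  if (nrow(keep) == 0L) stop("union produced an empty boundary")
  stitch_rings(keep, tol)
}

# stitch undirected boundary segments into closed rings; at junction vertices
# take the sharpest clockwise turn so rings stay simple
stitch_rings <- function(segs, tol = 1e-9) {
  vkey <- function(p) paste(p[1], p[2], sep = "|")
  n <- nrow(segs)
  ends <- vector("list", 2L * n)
  inc <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (e in list(segs[i, 1:2], segs[i, 3:4])) {
      k <- vkey(e)
      inc[[k]] <- c(if (!is.null(inc[[k]])) inc[[k]], i)
    }
  }
  used <- rep(FALSE, n)
  rings <- list()
  other_end <- function(i, p) {
    if (abs(segs[i, 1] - p[1]) < tol && abs(segs[i, 2] - p[2]) < tol) segs[i, 3:4] else segs[i, 1:2]
  }
  repeat {
    start <- which(!used)[1]
    if (is.na(start)) break
    used[start] <- TRUE
    ring <- list(segs[start, 1:2])
    cur <- segs[start, 3:4]
    prev <- segs[start, 1:2]
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 4L * n) stop("boundary stitching failed to close a ring")
      if (abs(cur[1] - ring[[1]][1]) < tol && abs(cur[2] - ring[[1]][2]) < tol) break
      ring[[length(ring) + 1L]] <- cur
      cand <- inc[[vkey(cur)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) stop("boundary stitching hit a dead end")
      if (length(cand) == 1L) {
        nxt <- cand
      } else {
        # choose the sharpest clockwise turn relative to the incoming direction
        din <- cur - prev
        ang_in <- atan2(din[2], din[1])
        best <- cand[1]; best_ang <- Inf
        for (ci in cand) {
          q <- other_end(ci, cur)
          dout <- q - cur
          a <- (atan2(dout[2], dout[1]) - ang_in) %% (2 * pi)
          if (a < best_ang) { best_ang <- a; best <- ci }
        }
        nxt <- best
      }
      used[nxt] <- TRUE
      prev <- cur
      cur <- other_end(nxt, cur)
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  rings
}

# assemble stitched rings into multipolygon parts: a ring whose inward-offset
# test point lies inside the source region is an outer ring, otherwise a hole;
# holes attach to the smallest enclosing outer ring
assemble_parts <- function(rings, region_parts, tol = 1e-9) {
  probe <- function(ring) {
    a <- ring[1, ]; b <- ring[2, ]
    mid <- (a + b) / 2
    d <- b - a
    len <- sqrt(sum(d^2))
    nrm <- c(-d[2], d[1]) / len
    eps <- max(len, 1) * 1e-6
    p1 <- mid + eps * nrm
    p2 <- mid - eps * nrm
    if (point_in_ring(p1, ring)) p1 else p2
  }
  is_outer <- logical(length(rings))
  probes <- vector("list", length(rings))
  for (i in seq_along(rings)) {
    p <- probe(rings[[i]])
    probes[[i]] <- p
    is_outer[i] <- point_in_multipolygon(p, lapply(region_parts, identity), tol)
  }
  outs <- which(is_outer)
  holes <- which(!is_outer)
  parts <- lapply(outs, function(i) list(rings[[i]]))
  if (length(holes)) {
    areas <- vapply(outs, function(i) abs(ring_signed_area(rings[[i]])), numeric(1))
    for (h in holes) {
      enclosing <- which(vapply(seq_along(outs), function(k) {
        point_in_ring(probes[[h]], rings[[outs[k]]])
      }, logical(1)))
      if (length(enclosing) == 0L) next  # sliver; drop
      k <- enclosing[which.min(areas[enclosing])]
      parts[[k]] <- c(parts[[k]], list(rings[[h]]))
    }
  }
  parts
}

# union a list of polygon parts assumed mutually non-overlapping; returns a
# multipolygon whose parts are the rook-connected blocks, each dissolved
union_parts <- function(parts, tol = 1e-9) {
  comp <- rook_components(parts, tol)
  out <- list()
  for (cc in sort(unique(comp))) {
    members <- parts[comp == cc]
    if (length(members) == 1L) {
      out <- c(out, list(orient_part(members[[1]])))
    } else {
      rings <- cancel_union(members, tol)
      merged <- assemble_parts(rings, members, tol)
      out <- c(out, lapply(merged, orient_part))
    }
  }
  out
}
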