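# Low-level planar polygon utilities used by the geography layer.
#
# A unit geometry is one or more simple rings, each an n x 2 numeric matrix
# of vertices in a planar projected coordinate system (km), stored unclosed.
# Multi-ring units arise when birthless sub-districts are unioned into a
# neighbour. Adjacency is derived by exact shared-segment matching, which is
# valid for vertex-matched tessellations such as the lattices produced by
# the scenario generator and the tessellations accepted on ingest.

# Normalise a geometry to a list of open rings.
#' @keywords internal
geom_rings <- function(g) {
  if (is.matrix(g)) list(ring_open(g)) else lapply(g, function(r) ring_open(as.matrix(r)))
}

#' @keywords internal
ring_close <- function(ring) {
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE))) {
    ring <- rbind(ring, ring[1, , drop = FALSE])
  }
  ring
}

#' @keywords internal
ring_open <- function(ring) {
  n <- nrow(ring)
  if (n > 1 && isTRUE(all.equal(ring[1, ], ring[n, ], check.attributes = FALSE))) {
    ring <- ring[-n, , drop = FALSE]
  }
  ring
}

# Shoelace area of a single ring.
#' @keywords internal
ring_area <- function(ring) {
  r <- ring_close(ring)
  x <- r[, 1]; y <- r[, 2]
  n <- nrow(r)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' @keywords internal
ring_centroid <- function(ring) {
  r <- ring_close(ring)
  x <- r[, 1]; y <- r[, 2]
  n <- nrow(r)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(ring_open(ring)))
  cx <- sum((x[-n] + x[-1]) * cross) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cross) / (6 * a)
  c(cx, cy)
}

#' @keywords internal
geom_area <- function(g) sum(vapply(geom_rings(g), ring_area, numeric(1)))

# Area-weighted centroid over rings.
#' @keywords internal
geom_centroid <- function(g) {
  rings <- geom_rings(g)
  cen <- t(vapply(rings, ring_centroid, numeric(2)))
  w <- vapply(rings, ring_area, numeric(1))
  if (sum(w) < 1e-12) w <- rep(1, length(rings))
  colSums(cen * w) / sum(w)
}

# Decompose a geometry into undirected segment keys plus lengths.
# Coordinates are rounded to a fixed tolerance so shared edges of a
# vertex-matched tessellation hash identically.
#' @keywords internal
geom_segments <- function(g, digits = 7) {
  purrr::map_dfr(geom_rings(g), function(ring) {
    r <- ring_close(ring)
    n <- nrow(r) - 1
    a <- round(r[seq_len(n), , drop = FALSE], digits)
    b <- round(r[seq_len(n) + 1, , drop = FALSE], digits)
    len <- sqrt(rowSums((b - a)^2))
    swap <- (a[, 1] > b[, 1]) | (a[, 1] == b[, 1] & a[, 2] > b[, 2])
    lo <- a; lo[swap, ] <- b[swap, , drop = FALSE]
    hi <- b; hi[swap, ] <- a[swap, , drop = FALSE]
    tibble::tibble(key = paste(lo[, 1], lo[, 2], hi[, 1], hi[, 2], sep = "|"),
                   length = len)
  })
}

#' @keywords internal
geom_vertex_keys <- function(g, digits = 7) {
  unique(unlist(lapply(geom_rings(g), function(ring) {
    r <- round(ring, digits)
    paste(r[, 1], r[, 2], sep = "|")
  })))
}

# Point-in-geometry membership (any ring). Boundary points may fall either
# way; callers use a first-match rule over units sorted by identifier.
#' @keywords internal
points_in_geom <- function(pts, g) {
  pts <- as.matrix(pts)
  if (nrow(pts) == 0) return(logical(0))
  hit <- rep(FALSE, nrow(pts))
  for (ring in geom_rings(g)) {
    todo <- which(!hit)
    if (!length(todo)) break
    hit[todo] <- mgcv::in.out(ring_close(ring), pts[todo, , drop = FALSE])
  }
  hit
}

#' @keywords internal
geom_bbox <- function(g) {
  m <- do.call(rbind, geom_rings(g))
  c(xmin = min(m[, 1]), xmax = max(m[, 1]),
    ymin = min(m[, 2]), ymax = max(m[, 2]))
}
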