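# Low-level planar geometry used by the network metrics. All coordinates are
# micrometres in a fixed lab frame (origin conventionally at the ring centre).

#' Path length of a polyline
#'
#' @param polyline Numeric matrix with two columns (x, y) in micrometres.
#' @return Total length in micrometres (sum of consecutive point distances).
#' @keywords internal
polyline_length <- function(polyline) {
  stopifnot(is.matrix(polyline), ncol(polyline) == 2)
  if (nrow(polyline) < 2) return(0)
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

#' Perimeter of a closed polygon
#'
#' The closing edge (last vertex back to first) is always included; the
#' polygon should not repeat its first vertex.
#' @keywords internal
polygon_perimeter <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2)
  if (nrow(poly) < 3) {
    stop_angioring("invalid_geometry", "polygon needs at least 3 vertices")
  }
  polyline_length(rbind(poly, poly[1, , drop = FALSE]))
}

# Distance from point p to the segment (a, b).
dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

# Shortest distance from p to the boundary of a closed polygon.
dist_point_polygon <- function(p, poly) {
  n <- nrow(poly)
  idx <- c(seq_len(n), 1L)
  min(vapply(seq_len(n), function(i) {
    dist_point_segment(p, poly[idx[i], ], poly[idx[i + 1L], ])
  }, numeric(1)))
}

# Simple polygon test: no two non-adjacent edges intersect. O(n^2); boundaries
# here have tens of vertices at most.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- function(i) {
    j <- if (i == n) 1L else i + 1L
    list(a = poly[i, ], b = poly[j, ])
  }
  intersects <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      si <- seg(i); sj <- seg(j)
      if (intersects(si$a, si$b, sj$a, sj$b)) return(FALSE)
    }
  }
  TRUE
}

# Cluster 2-D points whose pairwise distance is below `tol` (single linkage,
# union-find). Returns an integer cluster id per point.
cluster_points <- function(pts, tol) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tol2 <- tol^2
  for (i in seq_len(n - 1L)) {
    dx <- pts[(i + 1L):n, 1] - pts[i, 1]
    dy <- pts[(i + 1L):n, 2] - pts[i, 2]
    hits <- which(dx * dx + dy * dy <= tol2)
    for (j in hits + i) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Arclength position of the projection of point p onto a polyline. Used to
# order attachment events along a parent vessel. Vectorized over chords.
locate_on_polyline <- function(polyline, p) {
  n <- nrow(polyline)
  if (n < 2) return(0)
  a <- polyline[-n, , drop = FALSE]
  b <- polyline[-1, , drop = FALSE]
  abx <- b[, 1] - a[, 1]; aby <- b[, 2] - a[, 2]
  len2 <- abx * abx + aby * aby
  tt <- ((p[1] - a[, 1]) * abx + (p[2] - a[, 2]) * aby) / pmax(len2, 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  dx <- p[1] - (a[, 1] + tt * abx)
  dy <- p[2] - (a[, 2] + tt * aby)
  d2 <- dx * dx + dy * dy
  i <- which.min(d2)
  chord <- sqrt(len2)
  cum <- c(0, cumsum(chord))
  cum[i] + tt[i] * chord[i]
}

# Classed errors so callers can distinguish undefined parameters (empty
# networks) from genuine misuse.
stop_angioring <- function(class, message) {
  stop(structure(
    class = c(paste0("angioring_", class), "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
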