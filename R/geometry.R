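# Plain planar geometry for region maps: signed areas, point-in-polygon,
# and half-plane clipping with edge provenance labels. Polygons are n x 2
# matrices of vertices, open rings (last vertex != first), oriented either
# way; areas are returned unsigned.

#' Unsigned area of a polygon
#'
#' Shoelace area of an open-ring polygon matrix. Exported so callers can
#' audit the partition property of region maps (region areas summing to the
#' outline area).
#'
#' @param poly n x 2 vertex matrix (open ring).
#' @return unsigned area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

point_in_polygon <- function(pt, poly) {
  # even-odd ray casting
  x <- pt[1]; y <- pt[2]
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  crosses <- ((py > y) != (py[j] > y)) &
    (x < (px[j] - px) * (y - py) / (py[j] - py) + px)
  sum(crosses) %% 2 == 1
}

# Clip a labelled polygon by the half-plane of points closer to `p` than to
# `q` (the Voronoi bisector). `labels[i]` is the provenance of the edge from
# vertex i to vertex i+1 (-1 = outline, otherwise a neighbour region id).
# Newly created bisector edges are labelled `new_label`. Returns NULL when
# the intersection is (numerically) empty.
clip_bisector <- function(poly, labels, p, q, new_label) {
  d <- q - p
  m <- (p + q) / 2
  f <- as.vector((poly[, 1] - m[1]) * d[1] + (poly[, 2] - m[2]) * d[2])
  scale <- max(abs(f), 1e-12)
  inside <- f <= 1e-12 * scale
  if (all(inside)) return(list(poly = poly, labels = labels))
  if (!any(inside)) return(NULL)
  n <- nrow(poly)
  out_v <- vector("list", 2L * n)
  out_l <- integer(2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    if (inside[i]) {
      k <- k + 1L; out_v[[k]] <- a; out_l[k] <- labels[i]
      if (!inside[j]) {
        t <- f[i] / (f[i] - f[j])
        k <- k + 1L; out_v[[k]] <- a + t * (b - a); out_l[k] <- new_label
      }
    } else if (inside[j]) {
      t <- f[i] / (f[i] - f[j])
      k <- k + 1L; out_v[[k]] <- a + t * (b - a); out_l[k] <- labels[i]
    }
  }
  v <- do.call(rbind, out_v[seq_len(k)])
  l <- out_l[seq_len(k)]
  dedup_ring(v, l)
}

# Drop consecutive near-duplicate vertices (keeping the label of the edge
# that leaves the surviving vertex meaningful).
dedup_ring <- function(v, l, tol = 1e-10) {
  n <- nrow(v)
  if (n < 3) return(NULL)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i] && sqrt(sum((v[i, ] - v[j, ])^2)) < tol) keep[j] <- FALSE
  }
  v <- v[keep, , drop = FALSE]
  l <- l[keep]
  if (nrow(v) < 3) return(NULL)
  list(poly = v, labels = l)
}

# Uniform points inside a polygon by rejection from the bounding box.
sample_points_in_polygon <- function(n, poly) {
  lo <- apply(poly, 2, min)
  hi <- apply(poly, 2, max)
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    if (point_in_polygon(cand, poly)) {
      got <- got + 1L
      pts[got, ] <- cand
    }
  }
  pts
}
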