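#' Build a Voronoi region map
#'
#' Partitions a simple closed outline polygon into `n_regions` regions: seed
#' points are drawn uniformly inside the outline, each region is the Voronoi
#' cell of its seed point clipped to the outline, and region adjacency is
#' read off the shared (pre-noise) Voronoi edges. Cosmetic border noise —
#' a symmetric midpoint displacement on every interior edge — is then
#' applied identically on both sides of each border, so the regions still
#' partition the outline exactly.
#'
#' @param outline an n x 2 matrix of outline vertices (open ring). Defaults
#'   to the unit square. The outline should be convex or near-convex;
#'   strongly non-convex outlines may produce clipped cells that are not
#'   simple polygons.
#' @param n_regions number of regions (default 10).
#' @param seed integer seed; point placement and border noise are
#'   deterministic given the seed.
#' @param noise_amp border-noise amplitude as a fraction of the outline
#'   diameter (default 0.02); 0 disables border noise.
#' @return an object of class `region_map`: list with `regions` (list of
#'   n x 2 vertex matrices, ids 0..n-1), `adjacency` (symmetric logical
#'   matrix), `outline`, `points`, `seed`.
#' @examples
#' m <- build_region_map(n_regions = 10, seed = 7)
#' sum(vapply(m$regions, polygon_area, 0))  # == area of the unit square
#' @export
build_region_map <- function(outline = unit_square(), n_regions = 10L,
                             seed = 1L, noise_amp = 0.02) {
  outline <- as.matrix(outline)
  stopifnot(ncol(outline) == 2, n_regions >= 1)
  if (nrow(outline) >= 2 &&
      all(outline[1, ] == outline[nrow(outline), ])) {
    outline <- outline[-nrow(outline), , drop = FALSE]
  }
  if (nrow(outline) < 3 || polygon_area(outline) <= 0) {
    stop("degenerate outline: polygon has zero area")
  }
  n_regions <- as.integer(n_regions)

  if (n_regions == 1L) {
    adj <- matrix(FALSE, 1, 1)
    res <- structure(
      list(regions = list(outline), adjacency = adj,
           outline = outline, points = matrix(polygon_centroid(outline), 1),
           seed = as.integer(seed)),
      class = "region_map")
    return(res)
  }

  pts <- with_seed(substream_seed(seed, "geometry"),
                   sample_points_in_polygon(n_regions, outline))

  base_labels <- rep(-1L, nrow(outline))
  cells <- vector("list", n_regions)
  labels <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    cur <- list(poly = outline, labels = base_labels)
    for (j in seq_len(n_regions)) {
      if (j == i) next
      cur <- clip_bisector(cur$poly, cur$labels, pts[i, ], pts[j, ], j - 1L)
      if (is.null(cur)) {
        stop("Voronoi cell for region ", i - 1L,
             " degenerated to zero area (coincident points?)")
      }
    }
    cells[[i]] <- cur$poly
    labels[[i]] <- cur$labels
  }

  # adjacency from surviving bisector edges of positive length
  diam <- sqrt(sum((apply(outline, 2, max) - apply(outline, 2, min))^2))
  adj <- matrix(FALSE, n_regions, n_regions)
  for (i in seq_len(n_regions)) {
    v <- cells[[i]]; l <- labels[[i]]
    n <- nrow(v)
    nxt <- c(2:n, 1)
    len <- sqrt(rowSums((v[nxt, , drop = FALSE] - v)^2))
    nb <- unique(l[l >= 0 & len > 1e-9 * diam])
    adj[i, nb + 1L] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE

  if (noise_amp > 0) {
    cells <- add_border_noise(cells, labels, seed, noise_amp * diam)
  }

  structure(
    list(regions = cells, adjacency = adj, outline = outline,
         points = pts, seed = as.integer(seed)),
    class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map> ", length(x$regions), " regions, ",
      sum(x$adjacency) / 2, " adjacent pairs, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

unit_square <- function() {
  matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
}

# Symmetric midpoint displacement on interior edges. The displacement for a
# border is keyed on the unordered region pair, so the two regions sharing
# the border insert the identical jittered midpoint and the partition (and
# total area) is preserved exactly.
add_border_noise <- function(cells, labels, seed, amp) {
  n <- length(cells)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    v <- cells[[i]]; l <- labels[[i]]
    m <- nrow(v)
    nxt <- c(2:m, 1)
    pieces <- vector("list", m)
    for (e in seq_len(m)) {
      a <- v[e, ]; b <- v[nxt[e], ]
      if (l[e] >= 0) {
        j <- l[e] + 1L
        key <- substream_seed(seed, "border", min(i, j), max(i, j))
        disp <- with_seed(key, stats::runif(1, -1, 1)) * amp
        mid <- (a + b) / 2
        # canonical edge orientation so both sides displace identically
        # (rounded so the two cells' fp-identical-up-to-noise endpoints agree)
        ar <- round(a, 9); br <- round(b, 9)
        flip <- if (ar[1] > br[1] || (ar[1] == br[1] && ar[2] > br[2])) -1 else 1
        edge <- flip * (b - a)
        nrm <- c(-edge[2], edge[1])
        nl <- sqrt(sum(nrm^2))
        if (nl > 0) mid <- mid + disp * nrm / nl
        pieces[[e]] <- rbind(a, mid)
      } else {
        pieces[[e]] <- rbind(a)
      }
    }
    out[[i]] <- do.call(rbind, pieces)
  }
  out
}

#' Region adjacency as an edge list
#'
#' @param map a `region_map`.
#' @return two-column integer matrix of adjacent region-id pairs (0-based,
#'   each pair once).
#' @export
adjacency_pairs <- function(map) {
  idx <- which(map$adjacency & upper.tri(map$adjacency), arr.ind = TRUE)
  cbind(from = idx[, 1] - 1L, to = idx[, 2] - 1L)
}
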