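# Plain polygon geometry on pixel coordinates.  Polygons are n x 2
# matrices (columns x, y); the closing edge from the last to the first
# vertex is implicit.

#' Test points against a polygon
#'
#' Even-odd (ray casting) point-in-polygon test, vectorised over points.
#' Points lying exactly on a polygon edge (within `eps`) count as inside,
#' which makes downstream lamina assignment deterministic on boundaries.
#'
#' @param x,y numeric vectors of point coordinates.
#' @param poly numeric matrix with two columns (x, y); vertices in order,
#'   closing edge implicit.
#' @param eps tolerance for the on-edge test.
#' @return logical vector, one element per point.
#' @export
point_in_polygon <- function(x, y, poly, eps = 1e-9) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- length(x)
  stopifnot(length(y) == n)
  inside <- logical(n)
  on_edge <- logical(n)
  px <- poly[, 1]; py <- poly[, 2]
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
    # on-edge: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on <- abs(cross) <= eps * max(1, sqrt(seg_len2)) &
      x >= pmin(x1, x2) - eps & x <= pmax(x1, x2) + eps &
      y >= pmin(y1, y2) - eps & y <= pmax(y1, y2) + eps
    on_edge <- on_edge | on
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xint <- x1 + (y[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- x[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  inside | on_edge
}

#' Signed area of a polygon (shoelace formula)
#' @param poly two-column matrix of vertices.
#' @return signed area; positive when vertices run counter-clockwise in a
#'   y-up frame (clockwise in the y-down image frame).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), xmax = max(poly[, 1]),
    ymin = min(poly[, 2]), ymax = max(poly[, 2]))
}

# Proper-intersection test between segments p1-p2 and p3-p4 used by the
# simplicity check; shared endpoints of adjacent edges do not count.
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Is a polygon simple (non-self-intersecting)?
#' @param poly two-column vertex matrix.
#' @return `TRUE` if no two non-adjacent edges properly intersect.
#' @export
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  edges <- lapply(seq_len(n), function(i) {
    rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  })
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (.segments_cross(edges[[i]][1, ], edges[[i]][2, ],
                          edges[[j]][1, ], edges[[j]][2, ])) return(FALSE)
    }
  }
  TRUE
}

# Uniform rejection sampling of points inside a polygon.
sample_in_polygon <- function(n, poly, max_tries = 100 * n + 1000) {
  bb <- polygon_bbox(poly)
  out <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(out) < n && tries < max_tries) {
    m <- max(2 * (n - nrow(out)), 16)
    x <- runif(m, bb["xmin"], bb["xmax"])
    y <- runif(m, bb["ymin"], bb["ymax"])
    keep <- point_in_polygon(x, y, poly)
    out <- rbind(out, cbind(x[keep], y[keep]))
    tries <- tries + m
  }
  if (nrow(out) < n) stop("sample_in_polygon: rejection sampling failed")
  out[seq_len(n), , drop = FALSE]
}
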