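# Planar geometry for convex lease polygons on a metric grid.
#
# Leases are convex polygons (counter-clockwise vertex matrices, metres).
# Rasterised treatment/control masks need two predicates per 1 km pixel
# square: positive-area overlap with a polygon, and Euclidean distance to a
# polygon (a square intersects the d-buffered polygon iff its distance to the
# polygon is < d, because buffering a convex set is a Minkowski sum with a
# disc).

#' Build a convex polygon from a point cloud
#'
#' Returns the convex hull of the supplied points as a counter-clockwise
#' two-column matrix, the canonical polygon representation used throughout.
#'
#' @param x,y Numeric coordinate vectors (metres).
#' @return A matrix with columns `x`, `y`, one row per hull vertex (CCW).
#' @export
convex_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  h <- grDevices::chull(x, y)      # chull returns clockwise order
  m <- cbind(x = x[rev(h)], y = y[rev(h)])
  if (polygon_area(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

#' Signed area of a polygon
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly Two-column vertex matrix.
#' @return Signed area in square metres.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon centroid
#' @param poly Two-column vertex matrix.
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Test points for containment in a convex polygon
#'
#' Boundary points count as inside.
#'
#' @param poly CCW convex vertex matrix.
#' @param px,py Point coordinate vectors.
#' @return Logical vector.
#' @export
points_in_polygon <- function(poly, px, py) {
  n <- nrow(poly)
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
    cross <- ex * (py - poly[i, 2]) - ey * (px - poly[i, 1])
    inside <- inside & cross >= -1e-9
  }
  inside
}

# distance from points to a segment, vectorised over points
.dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 < .Machine$double.eps) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Euclidean distance from points to a convex polygon
#'
#' Zero for points inside or on the boundary.
#'
#' @param poly CCW convex vertex matrix.
#' @param px,py Point coordinate vectors.
#' @return Numeric vector of distances (metres).
#' @export
dist_points_polygon <- function(poly, px, py) {
  n <- nrow(poly)
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- pmin(d, .dist_point_segment(px, py, poly[i, 1], poly[i, 2],
                                     poly[j, 1], poly[j, 2]))
  }
  d[points_in_polygon(poly, px, py)] <- 0
  d
}

#' Distance from points to the nearest of several line segments
#'
#' Used for the distance-to-road covariate.
#'
#' @param segments Matrix with columns x0, y0, x1, y1, one row per segment.
#' @param px,py Point coordinate vectors.
#' @return Numeric vector of distances (metres); `Inf` if no segments.
#' @export
dist_points_segments <- function(segments, px, py) {
  d <- rep(Inf, length(px))
  if (is.null(segments) || nrow(segments) == 0) return(d)
  for (i in seq_len(nrow(segments))) {
    d <- pmin(d, .dist_point_segment(px, py, segments[i, 1], segments[i, 2],
                                     segments[i, 3], segments[i, 4]))
  }
  d
}

# distance from points to an axis-aligned square (centre cx,cy, half-edge h)
.dist_points_square <- function(px, py, cx, cy, h) {
  dx <- pmax(abs(px - cx) - h, 0)
  dy <- pmax(abs(py - cy) - h, 0)
  sqrt(dx * dx + dy * dy)
}

#' Positive-area overlap between pixel squares and a convex polygon
#'
#' Separating-axis test, vectorised over squares. With `strict = TRUE` (the
#' default) boundary contact does not count: the intersection must have
#' positive area, which is the "touching" rule used when rasterising leases.
#'
#' @param poly CCW convex vertex matrix.
#' @param cx,cy Square centre coordinate vectors.
#' @param half Half edge length of the squares (metres).
#' @param strict Require positive-area overlap (default) rather than contact.
#' @return Logical vector.
#' @export
squares_overlap_polygon <- function(poly, cx, cy, half, strict = TRUE) {
  n <- nrow(poly)
  axes <- matrix(0, n + 2, 2)
  axes[1, ] <- c(1, 0); axes[2, ] <- c(0, 1)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- c(poly[j, 1] - poly[i, 1], poly[j, 2] - poly[i, 2])
    axes[i + 2, ] <- c(-e[2], e[1])
  }
  tol <- if (strict) -1e-9 else 1e-9
  ok <- rep(TRUE, length(cx))
  for (a in seq_len(nrow(axes))) {
    ax <- axes[a, 1]; ay <- axes[a, 2]
    pr <- poly[, 1] * ax + poly[, 2] * ay
    pmin_ <- min(pr); pmax_ <- max(pr)
    c_ <- cx * ax + cy * ay
    r <- half * (abs(ax) + abs(ay))
    # overlap of [c - r, c + r] and [pmin_, pmax_]
    ov <- pmin(c_ + r, pmax_) - pmax(c_ - r, pmin_)
    ok <- ok & (ov > tol)
  }
  ok
}

#' Distance from pixel squares to a convex polygon
#'
#' Zero when the square and polygon overlap (including boundary contact);
#' otherwise the minimum Euclidean distance, attained at a vertex of one
#' shape against an edge of the other.
#'
#' @inheritParams squares_overlap_polygon
#' @return Numeric vector of distances (metres).
#' @export
dist_squares_polygon <- function(poly, cx, cy, half) {
  d <- rep(Inf, length(cx))
  # polygon vertices vs square interiors
  for (i in seq_len(nrow(poly))) {
    d <- pmin(d, .dist_points_square(poly[i, 1], poly[i, 2], cx, cy, half))
  }
  # square corners vs polygon
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) {
    d <- pmin(d, dist_points_polygon(poly, cx + sx * half, cy + sy * half))
  }
  d[squares_overlap_polygon(poly, cx, cy, half, strict = FALSE)] <- 0
  d
}

# shrink a convex polygon towards its centroid by factor f in (0, 1]
.shrink_polygon <- function(poly, f) {
  ct <- polygon_centroid(poly)
  cbind(x = ct[1] + f * (poly[, 1] - ct[1]),
        y = ct[2] + f * (poly[, 2] - ct[2]))
}
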