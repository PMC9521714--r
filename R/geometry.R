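## Planar geometry primitives shared by the SMLM and EM analyses.
## All coordinates are nanometres unless stated otherwise; polygons and
## contours are n x 2 matrices of vertices in order.

#' Construct a membrane contour
#'
#' A membrane contour is an ordered 2D polyline tracing a membrane in the
#' image plane (nm). Closed contours represent a full cross-section through a
#' spine head or shaft; open contours a partial membrane trace.
#'
#' @param vertices numeric matrix (n x 2) of vertex coordinates in nm.
#' @param closed logical; is the contour a closed polygon?
#' @return An object of class `membrane_contour`: the vertex matrix with
#'   attributes `closed` and `arc_length` (cumulative length at each vertex).
#' @export
membrane_contour <- function(vertices, closed = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("contour needs an n x 2 matrix with n >= 2")
  if (closed && nrow(vertices) < 3L)
    stop("a closed contour needs at least 3 vertices")
  if (!all(is.finite(vertices))) stop("contour vertices must be finite")
  seg <- contour_segments(vertices, closed)
  len <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2)
  if (any(len <= 0)) stop("contour has zero-length segments (repeated vertices)")
  structure(vertices,
            closed = closed,
            seg_length = len,
            arc_length = c(0, cumsum(len)),
            class = "membrane_contour")
}

# segment endpoints of a polyline; closed polylines wrap around
contour_segments <- function(vertices, closed) {
  n <- nrow(vertices)
  i0 <- if (closed) seq_len(n) else seq_len(n - 1L)
  i1 <- if (closed) c(seq_len(n)[-1L], 1L) else seq_len(n)[-1L]
  list(x0 = vertices[i0, 1], y0 = vertices[i0, 2],
       x1 = vertices[i1, 1], y1 = vertices[i1, 2])
}

#' Minimum distance from points to a membrane contour
#'
#' Computes the minimum Euclidean distance from each query point to the
#' contour, measured to the nearest point on any segment (not vertex-only).
#'
#' @param points numeric matrix (m x 2) or a length-2 vector, nm.
#' @param contour a [membrane_contour()] (or an n x 2 matrix, treated as
#'   closed).
#' @return Numeric vector of distances (nm) with attributes `segment` (index
#'   of the nearest segment for each point) and `arc_position` (arc-length
#'   coordinate of the nearest contour point, nm from the first vertex).
#' @examples
#' sq <- membrane_contour(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
#' point_to_contour_distance(c(50, -10), sq)  # 10
#' @export
point_to_contour_distance <- function(points, contour) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  if (!inherits(contour, "membrane_contour"))
    contour <- membrane_contour(as.matrix(contour), closed = TRUE)
  seg <- contour_segments(unclass(contour), attr(contour, "closed"))
  dx <- seg$x1 - seg$x0
  dy <- seg$y1 - seg$y0
  len2 <- dx^2 + dy^2
  m <- nrow(points)
  dist <- numeric(m)
  segment <- integer(m)
  tpar <- numeric(m)
  for (i in seq_len(m)) {
    # projection parameter of point onto each segment, clamped to [0, 1]
    t <- ((points[i, 1] - seg$x0) * dx + (points[i, 2] - seg$y0) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    qx <- seg$x0 + t * dx
    qy <- seg$y0 + t * dy
    d2 <- (points[i, 1] - qx)^2 + (points[i, 2] - qy)^2
    j <- which.min(d2)
    dist[i] <- sqrt(d2[j])
    segment[i] <- j
    tpar[i] <- t[j]
  }
  arc0 <- attr(contour, "arc_length")
  structure(dist,
            segment = segment,
            arc_position = arc0[segment] + tpar * attr(contour, "seg_length")[segment])
}

# Ray-casting point-in-polygon test, vectorized over points.
# Points exactly on the boundary may fall on either side; callers that care
# (zone assignment) treat near-zero contour distance as inside.
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  x0 <- poly[, 1]; y0 <- poly[, 2]
  x1 <- poly[c(2:n, 1), 1]; y1 <- poly[c(2:n, 1), 2]
  inside <- logical(length(px))
  for (i in seq_along(px)) {
    crosses <- ((y0 > py[i]) != (y1 > py[i])) &
      (px[i] < (x1 - x0) * (py[i] - y0) / (y1 - y0) + x0)
    inside[i] <- (sum(crosses) %% 2L) == 1L
  }
  inside
}

# Shoelace polygon area (absolute value)
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Convex hull of points as a polygon matrix (counter-clockwise)
convex_hull_polygon <- function(x, y) {
  h <- chull(x, y)
  cbind(x[h], y[h])
}

# Area-equivalent circle diameter from the convex hull of member points;
# degenerate hulls (< 3 distinct points, collinear) fall back to the maximum
# pairwise distance so the diameter stays positive for genuine clusters.
effective_diameter <- function(x, y) {
  a <- if (length(x) >= 3L) polygon_area(convex_hull_polygon(x, y)) else 0
  if (a > 0) return(2 * sqrt(a / pi))
  if (length(x) < 2L) return(0)
  max(stats::dist(cbind(x, y)))
}

# Uniform points in a polygon by rejection sampling from the bounding box;
# axis-aligned rectangles are sampled directly
runif_in_polygon <- function(n, poly) {
  poly <- as.matrix(poly)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  if (nrow(poly) == 4L &&
      abs(polygon_area(poly) - (xr[2] - xr[1]) * (yr[2] - yr[1])) < 1e-9)
    return(cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2])))
  out <- matrix(NA_real_, 0, 2)
  # acceptance ratio = polygon area / bbox area; guard against thin polygons
  frac <- max(polygon_area(poly) / ((xr[2] - xr[1]) * (yr[2] - yr[1])), 1e-3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / frac * 1.2) + 16L
    px <- runif(m, xr[1], xr[2])
    py <- runif(m, yr[1], yr[2])
    keep <- point_in_polygon(px, py, poly)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}
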