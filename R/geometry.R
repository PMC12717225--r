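# Planar geometry primitives shared by the subregion and gradient modules.
# All coordinates are micrometres; polygons are stored as open rings (first
# vertex not repeated at the end).

as_vertex_matrix <- function(polygon) {
  if (is.data.frame(polygon)) {
    check_columns(polygon, c("x_um", "y_um"), "polygon")
    polygon <- cbind(polygon$x_um, polygon$y_um)
  }
  if (!is.matrix(polygon) || ncol(polygon) != 2 || !is.numeric(polygon)) {
    stop("a polygon must be a numeric n x 2 matrix or a data frame with x_um/y_um")
  }
  if (!all(is.finite(polygon))) stop("polygon vertices must be finite")
  # drop a duplicated closing vertex if the caller supplied one
  n <- nrow(polygon)
  if (n > 1 && all(polygon[1, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  polygon
}

# Proper crossing test for segments p1-p2 and p3-p4 (shared endpoints and
# touching are not counted; vectorised over rows).
segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) {
    (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  }
  d1 <- o(p3, p4, p1); d2 <- o(p3, p4, p2)
  d3 <- o(p1, p2, p3); d4 <- o(p1, p2, p4)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

is_simple_polygon <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  adjacent <- (j == i + 1) | (i == 1 & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  !any(segments_cross(v[i, , drop = FALSE], v[nxt[i], , drop = FALSE],
                      v[j, , drop = FALSE], v[nxt[j], , drop = FALSE]))
}

#' Absolute polygon area by the shoelace formula
#'
#' @param polygon An n x 2 numeric matrix of vertices (ordered, ring open) or
#'   a data frame with `x_um`/`y_um` columns. Orientation is irrelevant.
#' @param validate Check simplicity (no self-intersection); default `TRUE`.
#' @return Area in square micrometres.
#' @export
polygon_area <- function(polygon, validate = TRUE) {
  v <- as_vertex_matrix(polygon)
  n <- nrow(v)
  if (n < 3) stop("a polygon needs at least 3 vertices")
  if (validate && !is_simple_polygon(v)) stop("polygon is self-intersecting")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Distance from points to a segment a-b; vectorised over points.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx; qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

#' Even-odd point-in-polygon test with closed boundary
#'
#' Points on the boundary (within `tol`) count as inside, so thin regions do
#' not lose cells sitting exactly on a digitised border.
#'
#' @param px,py Point coordinates (vectors of equal length).
#' @param polygon Vertex matrix or data frame (see [polygon_area()]).
#' @param tol Boundary tolerance in µm.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, polygon, tol = 1e-9) {
  v <- as_vertex_matrix(polygon)
  n <- nrow(v)
  if (n < 3) stop("a polygon needs at least 3 vertices")
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    on_edge <- on_edge | point_segment_distance(px, py, xi, yi, xj, yj) <= tol
    j <- i
  }
  inside | on_edge
}

#' Distance from points to the boundary of a polygon
#'
#' @inheritParams point_in_polygon
#' @return Numeric vector of distances in µm (0 only for points exactly on
#'   the boundary; combine with [point_in_polygon()] for signed semantics).
#' @export
polygon_boundary_distance <- function(px, py, polygon) {
  v <- as_vertex_matrix(polygon)
  n <- nrow(v)
  d <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    d <- pmin(d, point_segment_distance(px, py, v[i, 1], v[i, 2], v[j, 1], v[j, 2]))
    j <- i
  }
  d
}

#' Regular polygon approximation of a circle
#'
#' @param cx,cy Centre in µm.
#' @param r Radius in µm.
#' @param n Number of vertices (default 64).
#' @return An n x 2 vertex matrix (counter-clockwise).
#' @export
circle_polygon <- function(cx, cy, r, n = 64) {
  if (r <= 0) stop("radius must be positive")
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

#' Annulus as a single simple polygon
#'
#' The ring between `r_in` and `r_out` is cut open by a slit of half-width
#' `slit` µm on the positive x-axis, so the outer ring (counter-clockwise)
#' and the inner ring (clockwise) join into one simple polygon. The slit is
#' microscopically thin: the shoelace area differs from the true annulus area
#' by about `2 * slit * (r_out - r_in)` µm².
#'
#' @param cx,cy Centre in µm.
#' @param r_in,r_out Inner and outer radii in µm, `0 < r_in < r_out`.
#' @param n Vertices per ring (default 64).
#' @param slit Slit half-width in µm.
#' @return A 2n x 2 vertex matrix.
#' @export
annulus_polygon <- function(cx, cy, r_in, r_out, n = 64, slit = 1e-3) {
  if (!(r_in > 0 && r_out > r_in)) stop("need 0 < r_in < r_out")
  a_out <- asin(min(1, slit / r_out))
  a_in <- asin(min(1, slit / r_in))
  th_out <- seq(a_out, 2 * pi - a_out, length.out = n)
  th_in <- seq(2 * pi - a_in, a_in, length.out = n)
  rbind(
    cbind(cx + r_out * cos(th_out), cy + r_out * sin(th_out)),
    cbind(cx + r_in * cos(th_in), cy + r_in * sin(th_in))
  )
}
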