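#' Planar geometry primitives
#'
#' All coordinates in the package are planar meters (projected); every
#' distance and area is Euclidean. These helpers back the buffer classifier
#' and the isopleth membership tests.
#'
#' @name geometry
#' @keywords internal
NULL

#' Distance from points to a line segment
#'
#' Shortest Euclidean distance from one or more points to the closed segment
#' from `(ax, ay)` to `(bx, by)`. Vectorised over the points.
#'
#' @param px,py point coordinates (meters), equal-length vectors.
#' @param ax,ay,bx,by segment endpoints (meters), scalars.
#' @return numeric vector of distances in meters.
#' @export
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  L2 <- dx * dx + dy * dy
  if (L2 == 0) {
    return(sqrt((px - ax)^2 + (py - ay)^2))
  }
  t <- ((px - ax) * dx + (py - ay) * dy) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Minimum distance from one point to many segments (vectorised over segments).
seg_dmin_vec <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  t <- ifelse(L2 > 0, ((px - x1) * dx + (py - y1) * dy) / L2, 0)
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Does a segment interact with a circle?
#'
#' `mode = "closed"` flags any contact with the closed disc (crossing or
#' full containment); `mode = "boundary"` flags only segments that touch the
#' circle boundary itself (the minimum distance is at most r while some point
#' of the segment lies at distance at least r).
#'
#' @param x1,y1,x2,y2 segment endpoints (meters).
#' @param cx,cy circle center (meters).
#' @param r radius (meters).
#' @param mode `"closed"` or `"boundary"`.
#' @return logical scalar.
#' @export
segment_intersects_circle <- function(x1, y1, x2, y2, cx, cy, r,
                                      mode = c("closed", "boundary")) {
  mode <- match.arg(mode)
  dmin <- dist_point_segment(cx, cy, x1, y1, x2, y2)
  if (mode == "closed") {
    return(dmin <= r)
  }
  dmax <- max(sqrt((x1 - cx)^2 + (y1 - cy)^2), sqrt((x2 - cx)^2 + (y2 - cy)^2))
  dmin <= r && dmax >= r
}

# Even-odd point-in-ring test with an explicit on-edge check: points on the
# boundary count as inside. `ring` is a list/data.frame with x, y (closed or
# open; closure is implied).
point_in_ring <- function(px, py, ring, eps = 1e-9) {
  x <- ring$x
  y <- ring$y
  n <- length(x)
  if (n < 3) return(FALSE)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
    if (n < 3) return(FALSE)
  }
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # on-edge check
    d <- dist_point_segment(px, py, x[j], y[j], x[i], y[i])
    if (d <= eps) return(NA) # sentinel: boundary
    if ((y[i] > py) != (y[j] > py)) {
      xint <- (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Even-odd containment in a set of rings
#'
#' Multi-part polygons with holes are represented as a flat list of rings;
#' containment is decided by even-odd parity across all rings. Points on any
#' ring boundary count as inside.
#'
#' @param px,py point coordinates (meters), scalars.
#' @param rings list of rings, each with `x` and `y` components.
#' @param eps on-edge tolerance in meters.
#' @return logical scalar.
#' @export
point_in_rings <- function(px, py, rings, eps = 1e-9) {
  parity <- FALSE
  for (ring in rings) {
    r <- point_in_ring(px, py, ring, eps = eps)
    if (is.na(r)) return(TRUE) # boundary counts as in
    parity <- xor(parity, r)
  }
  parity
}

# Proper/touching intersection of segments p1-p2 and p3-p4.
segments_cross <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  orient <- function(ax, ay, bx, by, cx, cy) {
    v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    sign(v)
  }
  o1 <- orient(x1, y1, x2, y2, x3, y3)
  o2 <- orient(x1, y1, x2, y2, x4, y4)
  o3 <- orient(x3, y3, x4, y4, x1, y1)
  o4 <- orient(x3, y3, x4, y4, x2, y2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(ax, ay, bx, by, px, py) {
    min(ax, bx) - 1e-12 <= px && px <= max(ax, bx) + 1e-12 &&
      min(ay, by) - 1e-12 <= py && py <= max(ay, by) + 1e-12
  }
  (o1 == 0 && on_seg(x1, y1, x2, y2, x3, y3)) ||
    (o2 == 0 && on_seg(x1, y1, x2, y2, x4, y4)) ||
    (o3 == 0 && on_seg(x3, y3, x4, y4, x1, y1)) ||
    (o4 == 0 && on_seg(x3, y3, x4, y4, x2, y2))
}

#' Does a segment interact with a polygonal region?
#'
#' The region is the even-odd interior of `rings`. `mode = "closed"` counts
#' any contact (edge crossing or an endpoint inside); `mode = "boundary"`
#' requires the segment to cross or touch a ring edge.
#'
#' @inheritParams segment_intersects_circle
#' @param rings list of rings (each with `x`, `y`).
#' @return logical scalar.
#' @export
segment_intersects_polygon <- function(x1, y1, x2, y2, rings,
                                       mode = c("closed", "boundary")) {
  mode <- match.arg(mode)
  for (ring in rings) {
    rx <- ring$x
    ry <- ring$y
    n <- length(rx)
    if (n < 2) next
    if (!(rx[1] == rx[n] && ry[1] == ry[n])) {
      rx <- c(rx, rx[1]); ry <- c(ry, ry[1]); n <- n + 1
    }
    for (i in seq_len(n - 1)) {
      if (segments_cross(x1, y1, x2, y2, rx[i], ry[i], rx[i + 1], ry[i + 1])) {
        return(TRUE)
      }
    }
  }
  if (mode == "closed") {
    if (point_in_rings(x1, y1, rings) || point_in_rings(x2, y2, rings)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Signed shoelace area of a ring
#'
#' @param ring a list with `x`, `y` vertex coordinates (meters).
#' @return area in square meters (absolute value).
#' @keywords internal
ring_area <- function(ring) {
  x <- ring$x
  y <- ring$y
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
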