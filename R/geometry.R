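# Planar geometry primitives for buffer analysis. All coordinates are in a
# projected metric CRS; polygons are single rings given as n x 2 matrices
# (closed or open), polylines as n x 2 matrices.

# Signed area of a ring (shoelace); positive = counter-clockwise.
.ring_signed_area <- function(ring) {
  ring <- .close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

.close_ring <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Area of the intersection of a polygon with a disc
#'
#' Exact (Green's theorem with circular-arc substitution) area of
#' `polygon intersect disc(center, radius)`; no discretisation, so results
#' are invariant under rotation of the scene to floating-point accuracy.
#'
#' @param ring n x 2 matrix of polygon vertices (single ring, any
#'   orientation, closed or open).
#' @param center Length-2 numeric, disc center.
#' @param radius Disc radius (> 0).
#' @return Intersection area in squared input units.
#' @export
circle_polygon_area <- function(ring, center, radius) {
  ring <- .close_ring(ring)
  if (.ring_signed_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), ]
  p <- sweep(ring, 2, center)
  n <- nrow(p) - 1L
  total <- 0
  r2 <- radius^2
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[i + 1L, ]
    d <- b - a
    dd <- sum(d * d)
    if (dd == 0) next
    # segment-circle intersection parameters
    tb <- numeric(0)
    disc <- (sum(a * d))^2 - dd * (sum(a * a) - r2)
    if (disc > 0) {
      sq <- sqrt(disc)
      t1 <- (-sum(a * d) - sq) / dd
      t2 <- (-sum(a * d) + sq) / dd
      tb <- c(t1, t2)
      tb <- tb[tb > 1e-12 & tb < 1 - 1e-12]
    }
    ts <- sort(unique(c(0, tb, 1)))
    for (k in seq_len(length(ts) - 1L)) {
      u <- ts[k]; v <- ts[k + 1L]
      pp <- a + u * d; qq <- a + v * d
      mid <- a + 0.5 * (u + v) * d
      if (sum(mid * mid) <= r2) {
        total <- total + 0.5 * (pp[1] * qq[2] - pp[2] * qq[1])
      } else {
        dth <- atan2(qq[2], qq[1]) - atan2(pp[2], pp[1])
        if (dth > pi) dth <- dth - 2 * pi
        if (dth < -pi) dth <- dth + 2 * pi
        total <- total + 0.5 * r2 * dth
      }
    }
  }
  max(total, 0)
}

#' Clip a polyline to a disc
#'
#' @param coords n x 2 matrix of polyline vertices.
#' @inheritParams circle_polygon_area
#' @return List of n x 2 matrices, one per connected piece inside the disc
#'   (possibly empty). A piece that enters and leaves repeatedly is split.
#' @export
clip_polyline_to_circle <- function(coords, center, radius) {
  p <- sweep(coords, 2, center)
  r2 <- radius^2
  pieces <- list(); cur <- NULL
  push <- function(pt) {
    pt_abs <- pt + center
    if (is.null(cur)) cur <<- matrix(pt_abs, 1, 2)
    else if (sum((cur[nrow(cur), ] - pt_abs)^2) > 1e-18) cur <<- rbind(cur, pt_abs)
  }
  finish <- function() {
    if (!is.null(cur) && nrow(cur) >= 2L) pieces[[length(pieces) + 1L]] <<- cur
    cur <<- NULL
  }
  n <- nrow(p)
  for (i in seq_len(n - 1L)) {
    a <- p[i, ]; b <- p[i + 1L, ]
    d <- b - a; dd <- sum(d * d)
    if (dd == 0) next
    # the disc is convex: the inside part of a segment is a single interval
    cc <- sum(a * a) - r2
    disc <- (sum(a * d))^2 - dd * cc
    if (disc <= 0) {            # no crossing: fully inside or fully outside
      if (cc <= 0) { push(a); push(b) } else finish()
      next
    }
    sq <- sqrt(disc)
    t0 <- (-sum(a * d) - sq) / dd
    t1 <- (-sum(a * d) + sq) / dd
    lo <- max(0, t0); hi <- min(1, t1)
    if (lo >= hi) { finish(); next }   # inside interval does not meet [0, 1]
    if (lo > 0) finish()               # segment enters the disc: new piece
    push(a + lo * d)
    push(a + hi * d)
    if (hi < 1) finish()               # segment leaves the disc
  }
  finish()
  pieces
}

# Total length of a polyline.
.polyline_length <- function(coords) {
  if (is.null(coords) || nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums((coords[-1, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE])^2)))
}

# Point at half the arc length of a polyline.
.polyline_midpoint <- function(coords) {
  seg <- coords[-1, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  cum <- cumsum(len)
  half <- cum[length(cum)] / 2
  i <- which(cum >= half)[1]
  prev <- if (i == 1L) 0 else cum[i - 1L]
  frac <- if (len[i] == 0) 0 else (half - prev) / len[i]
  coords[i, ] + frac * seg[i, ]
}

#' Parallel and orthogonal length components of a clipped linear element
#'
#' The reference axis is the unit vector from the buffer center (the pollen
#' receptor) to the element's midpoint, the point at half its arc length
#' after clipping. Each segment vector `v` contributes `|v . u|` to the
#' parallel and `|v . n|` to the orthogonal component (`u` the axis, `n`
#' its normal).
#'
#' @param coords n x 2 matrix: one clipped element piece.
#' @param center Length-2 numeric: the receptor position.
#' @return Named numeric `c(parallel, orthogonal)` in meters; `NA` if the
#'   midpoint coincides with the center (axis undefined; caller skips the
#'   element with a warning).
#' @export
op_components <- function(coords, center) {
  if (nrow(coords) < 2L) return(c(parallel = 0, orthogonal = 0))
  mid <- .polyline_midpoint(coords)
  axis <- mid - center
  na <- sqrt(sum(axis^2))
  if (na < 1e-9) return(c(parallel = NA_real_, orthogonal = NA_real_))
  u <- axis / na
  nv <- c(-u[2], u[1])
  seg <- coords[-1, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE]
  c(parallel = sum(abs(seg %*% u)), orthogonal = sum(abs(seg %*% nv)))
}

# Ray-casting point-in-polygon (ring matrix, open or closed).
.point_in_ring <- function(pt, ring) {
  ring <- .close_ring(ring)
  x <- pt[1]; y <- pt[2]
  n <- nrow(ring) - 1L
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    if ((y1 > y) != (y2 > y)) {
      xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      if (x < xint) inside <- !inside
    }
  }
  inside
}

# Distance from a point to a segment.
.point_seg_dist <- function(pt, a, b) {
  d <- b - a
  dd <- sum(d * d)
  t <- if (dd == 0) 0 else max(0, min(1, sum((pt - a) * d) / dd))
  sqrt(sum((a + t * d - pt)^2))
}

#' Distance from a point to a polygon boundary
#'
#' @param pt Length-2 numeric.
#' @param ring n x 2 polygon ring matrix.
#' @return Minimum Euclidean distance from `pt` to the ring (0 on the ring;
#'   positive inside and outside alike).
#' @export
point_polygon_boundary_distance <- function(pt, ring) {
  ring <- .close_ring(ring)
  n <- nrow(ring) - 1L
  min(vapply(seq_len(n), function(i) {
    .point_seg_dist(pt, ring[i, ], ring[i + 1L, ])
  }, numeric(1)))
}

# Distance from a point to a polygon (0 if inside).
.point_polygon_distance <- function(pt, ring) {
  if (.point_in_ring(pt, ring)) 0 else point_polygon_boundary_distance(pt, ring)
}
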