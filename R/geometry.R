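# Minimal planar geometry kernel for the availability polygon.
#
# Only what the sampling design needs: convex hulls, polygon area, point-in-
# polygon tests, and clipping a convex subject polygon against convex clip
# polygons (Sutherland-Hodgman). Ocean masks are therefore restricted to
# unions of disjoint convex polygons (the synthetic coastline is a
# rectangle), a constraint documented on mcp_available_area().

# Signed area by the shoelace formula; vertices as a 2-column matrix.
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Point-in-polygon test
#'
#' Ray-casting test; points on the boundary count as inside (within a small
#' tolerance).
#'
#' @param x,y Point coordinates.
#' @param poly Two-column vertex matrix.
#' @return Logical vector.
#' @export
points_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  # count boundary vertices/edges as inside (within tolerance)
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    dx <- px[i] - px[j]; dy <- py[i] - py[j]
    len2 <- dx^2 + dy^2
    if (len2 > 0) {
      t <- ((x - px[j]) * dx + (y - py[j]) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (x - (px[j] + t * dx))^2 + (y - (py[j] + t * dy))^2
      on_edge <- on_edge | d2 < 1e-18 * max(1, len2)
    }
    j <- i
  }
  inside | on_edge
}

# Sutherland-Hodgman: clip a polygon by one convex clip polygon (counter-
# clockwise orientation enforced internally). Returns the intersection
# polygon (possibly with 0 rows).
clip_convex <- function(subject, clip) {
  ccw <- function(p) {
    n <- nrow(p)
    j <- c(n, seq_len(n - 1))
    s <- sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2]) / 2
    if (s < 0) p[rev(seq_len(n)), , drop = FALSE] else p
  }
  clip <- ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(inp)
    for (i in seq_len(n)) {
      cur <- inp[i, ]; prev <- inp[if (i == 1) n else i - 1, ]
      sc <- side(cur); sp <- side(prev)
      if (sc >= -1e-12) {
        if (sp < -1e-12) out <- rbind(out, intersect_seg(prev, cur, a, c(ex, ey)))
        out <- rbind(out, cur)
      } else if (sp >= -1e-12) {
        out <- rbind(out, intersect_seg(prev, cur, a, c(ex, ey)))
      }
    }
  }
  out
}

# Intersection of segment p->q with the infinite line through a with
# direction d.
intersect_seg <- function(p, q, a, d) {
  # solve p + t (q - p) on line: cross(d, x - a) = 0
  rx <- q[1] - p[1]; ry <- q[2] - p[2]
  denom <- d[1] * ry - d[2] * rx
  t <- if (abs(denom) < 1e-300) 0 else
    (d[1] * (a[2] - p[2]) - d[2] * (a[1] - p[1])) / denom
  c(p[1] + t * rx, p[2] + t * ry)
}

#' Availability polygon: 100% MCP minus ocean
#'
#' Delineates available habitat as the 100% minimum convex polygon around all
#' summer used locations (1 Jun - 31 Aug), with any area overlapping the
#' ocean removed. The ocean mask must be supplied as a list of disjoint
#' convex polygons (2-column vertex matrices); the synthetic coastline is a
#' rectangle, which satisfies this. The forage prediction-area mask is applied
#' later, at sampling time, on the cell grid.
#'
#' @param points Data frame of used locations with `x`, `y` (at least 3
#'   non-collinear points).
#' @param ocean Optional list of convex polygons to subtract (or a single
#'   2-column matrix).
#' @return An object of class `mcp_area`: list with `hull` (vertex matrix),
#'   `ocean`, and `area` (hull area minus ocean overlap, squared map units).
#' @export
mcp_available_area <- function(points, ocean = NULL) {
  stopifnot(is.data.frame(points) || is.matrix(points))
  xy <- cbind(points[["x"]] %||% points[, 1], points[["y"]] %||% points[, 2])
  xy <- unique(xy[stats::complete.cases(xy), , drop = FALSE])
  if (nrow(xy) < 3) stopf("MCP requires at least 3 distinct points")
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  if (polygon_area(hull) <= 0) stopf("MCP is degenerate: points are collinear")
  if (!is.null(ocean) && is.matrix(ocean)) ocean <- list(ocean)
  cut_area <- 0
  for (oc in ocean %||% list()) {
    cut_area <- cut_area + polygon_area(clip_convex(hull, oc))
  }
  structure(
    list(hull = hull, ocean = ocean, area = polygon_area(hull) - cut_area),
    class = "mcp_area"
  )
}

#' @export
print.mcp_area <- function(x, ...) {
  cat(sprintf(
    "<mcp_area> %d hull vertices, area %.4g (hull %.4g, ocean removed %.4g)\n",
    nrow(x$hull), x$area, polygon_area(x$hull), polygon_area(x$hull) - x$area
  ))
  invisible(x)
}
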