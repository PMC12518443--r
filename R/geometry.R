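#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Determines for each point whether it lies inside a polygon under the
#' even-odd (ray crossing) rule. Points exactly on a polygon edge or vertex
#' count as inside. The polygon is implicitly closed (the last vertex
#' connects back to the first) and may self-intersect; for self-intersecting
#' polygons the even-odd rule still yields a deterministic answer.
#'
#' @param x,y Numeric vectors of point coordinates (pixels, image
#'   convention: origin top-left, y downward — the test itself is
#'   orientation-agnostic).
#' @param polygon Two-column numeric matrix of polygon vertices, at least 3
#'   rows.
#' @return Logical vector, one element per point.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) {
    stop("polygon must have at least 3 vertices", call. = FALSE)
  }
  px <- polygon[, 1]
  py <- polygon[, 2]
  n <- length(px)
  nxt <- c(seq_len(n)[-1], 1L)
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  for (i in seq_len(n)) {
    x1 <- px[i]; y1 <- py[i]
    x2 <- px[nxt[i]]; y2 <- py[nxt[i]]
    # boundary check: point collinear with and within the segment's bbox
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    seg <- cross == 0 &
      x >= pmin(x1, x2) & x <= pmax(x1, x2) &
      y >= pmin(y1, y2) & y <= pmax(y1, y2)
    on_edge <- on_edge | seg
    # even-odd ray crossing: horizontal ray towards +x
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

# Piecewise-linear interpolation of (frame, x, y) waypoints at given frames.
# Constant extrapolation outside the waypoint span.
.interp_waypoints <- function(waypoints, frames) {
  wf <- waypoints$frame
  if (length(wf) == 1L) {
    return(list(x = rep(waypoints$x, length(frames)),
                y = rep(waypoints$y, length(frames))))
  }
  list(
    x = stats::approx(wf, waypoints$x, xout = frames, rule = 2)$y,
    y = stats::approx(wf, waypoints$y, xout = frames, rule = 2)$y)
}
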