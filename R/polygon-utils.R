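# Internal polygon helpers. Polygons are lists with numeric x, y of equal
# length, vertices in order, closing edge implicit (last -> first).

poly_signed_area <- function(x, y) {
  0.5 * sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
}

poly_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
}

# 3-point (w = 1) circular moving average; suppresses the half-pixel
# marching-squares zigzag without eroding features larger than ~2 px.
smooth_closed_polygon <- function(x, y, w = 1L) {
  n <- length(x)
  if (w < 1L || n < 2L * w + 5L) {
    return(list(x = x, y = y))
  }
  idx <- outer(seq_len(n), (-w):w, "+")
  idx <- ((idx - 1L) %% n) + 1L
  list(x = rowMeans(matrix(x[idx], n)), y = rowMeans(matrix(y[idx], n)))
}

ensure_ccw <- function(p) {
  if (poly_signed_area(p$x, p$y) < 0) {
    p$x <- rev(p$x)
    p$y <- rev(p$y)
  }
  p
}

convex_hull <- function(x, y) {
  i <- grDevices::chull(x, y)
  list(x = x[i], y = y[i])
}

# Minimum distance from point (px, py) to each closed-polygon edge.
point_to_polygon_dist <- function(px, py, x, y) {
  x2 <- c(x[-1L], x[1L])
  y2 <- c(y[-1L], y[1L])
  dx <- x2 - x
  dy <- y2 - y
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  t <- pmin(1, pmax(0, ((px - x) * dx + (py - y) * dy) / len2))
  qx <- x + t * dx
  qy <- y + t * dy
  min(sqrt((px - qx)^2 + (py - qy)^2))
}

# Total chord length of the infinite line through (cx, cy) at `theta` radians
# (direction (cos, sin)) across the polygon: intersections with all edges,
# sorted along the line, summed in entry/exit pairs. Returns NA when the line
# misses the polygon.
line_polygon_chord <- function(cx, cy, theta, x, y) {
  dx <- cos(theta)
  dy <- sin(theta)
  rx <- x - cx
  ry <- y - cy
  s <- rx * dy - ry * dx          # signed offset from the line
  s[s == 0] <- 1e-12              # nudge exact hits off the line
  t <- rx * dx + ry * dy          # position along the line
  s2 <- c(s[-1L], s[1L])
  t2 <- c(t[-1L], t[1L])
  cross <- s * s2 < 0
  if (!any(cross)) {
    return(NA_real_)
  }
  f <- s[cross] / (s[cross] - s2[cross])
  ts <- t[cross] + f * (t2[cross] - t[cross])
  if (length(ts) == 2L) {         # convex fast path
    return(abs(ts[2L] - ts[1L]))
  }
  ts <- sort.int(ts, method = "quick")
  if (length(ts) %% 2L == 1L) {   # numerically degenerate vertex grazing
    return(max(ts) - min(ts))
  }
  sum(ts[seq(2L, length(ts), by = 2L)] - ts[seq(1L, length(ts), by = 2L)])
}

# Even-odd scanline rasterization of a polygon onto the integer pixel grid.
# Returns a logical matrix covering rows r0..r1, cols c0..c1 (0-based), with
# attributes r0/c0 giving the offset.
rasterize_polygon <- function(x, y) {
  r0 <- floor(min(y))
  r1 <- ceiling(max(y))
  c0 <- floor(min(x))
  c1 <- ceiling(max(x))
  nr <- r1 - r0 + 1L
  nc <- c1 - c0 + 1L
  m <- matrix(FALSE, nr, nc)
  x2 <- c(x[-1L], x[1L])
  y2 <- c(y[-1L], y[1L])
  for (r in seq_len(nr)) {
    yy <- r0 + r - 1
    hit <- (y <= yy & y2 > yy) | (y2 <= yy & y > yy)  # half-open: no double count
    if (!any(hit)) next
    xs <- sort(x[hit] + (yy - y[hit]) / (y2[hit] - y[hit]) * (x2[hit] - x[hit]))
    k <- length(xs)
    if (k < 2L) next
    for (j in seq(1L, k - 1L, by = 2L)) {
      a <- ceiling(xs[j] - c0)      # first pixel centre inside the span
      b <- floor(xs[j + 1L] - c0)
      if (b >= a) m[r, (a + 1L):(b + 1L)] <- TRUE
    }
  }
  attr(m, "r0") <- r0
  attr(m, "c0") <- c0
  m
}
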