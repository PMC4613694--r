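# Rasterized reference shapes and brute-force oracles used across tests.

disc_mask <- function(r, pad = 5L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad
  d2 <- outer((0:(n - 1L)) - c0, (0:(n - 1L)) - c0,
              function(a, b) a^2 + b^2)
  (d2 <= r^2) * 1
}

rect_mask <- function(h, w, pad = 5L) {
  m <- matrix(0, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- 1
  m
}

# solid ellipse, semi-axis a along x (columns), b along y (rows)
ellipse_mask <- function(a, b, pad = 5L) {
  nr <- 2L * (b + pad) + 1L
  nc <- 2L * (a + pad) + 1L
  d2 <- outer((((0:(nr - 1L)) - (b + pad)) / b)^2,
              (((0:(nc - 1L)) - (a + pad)) / a)^2, "+")
  (d2 <= 1) * 1
}

# random simple star-shaped polygon (smooth radial perturbation)
random_blob_poly <- function(seed, r_base = 20, amp = 0.25) {
  set.seed(seed)
  t <- seq(0, 2 * pi, length.out = 91L)[-91L]
  k <- 2:6
  ck <- rnorm(5L, 0, amp / 3)
  rho <- r_base * (1 + as.vector(cos(outer(t, k) +
    rep(runif(5L, 0, 2 * pi), each = length(t))) %*% ck))
  list(x = rho * cos(t), y = rho * sin(t))
}

poly_to_mask <- function(poly) {
  m <- cellmorph:::rasterize_polygon(poly$x, poly$y)
  m * 1
}

random_blob_mask <- function(seed, r_base = 20, amp = 0.25) {
  poly_to_mask(random_blob_poly(seed, r_base, amp))
}

rotate_poly <- function(poly, deg) {
  th <- deg * pi / 180
  list(x = poly$x * cos(th) - poly$y * sin(th),
       y = poly$x * sin(th) + poly$y * cos(th))
}

# --- independent oracles -----------------------------------------------

# trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(pos, neg) {
  th <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1L))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1L))
  sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
}

# brute-force two-sample KS D over all pooled evaluation points
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1L))))
}

# brute-force second central moments of a pixel set -> ellipse axes
brute_moment_axes <- function(pixels) {
  px <- pixels[, "col"]
  py <- pixels[, "row"]
  mxx <- mean((px - mean(px))^2)
  myy <- mean((py - mean(py))^2)
  mxy <- mean((px - mean(px)) * (py - mean(py)))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L), symmetric = TRUE)$values
  c(major = 4 * sqrt(ev[1L]), minor = 4 * sqrt(ev[2L]))
}

# numeric arc length of an ellipse by dense polygonal approximation
dense_ellipse_perimeter <- function(a, b, n = 2e5) {
  t <- seq(0, 2 * pi, length.out = n + 1L)
  sum(sqrt(diff(a * cos(t))^2 + diff(b * sin(t))^2))
}

# minimum distance from a point to a segment (scalar oracle)
seg_dist <- function(px, py, ax, ay, bx, by) {
  t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
    max((bx - ax)^2 + (by - ay)^2, 1e-300)
  t <- min(1, max(0, t))
  sqrt((px - (ax + t * (bx - ax)))^2 + (py - (ay + t * (by - ay)))^2)
}
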