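#' Geometry configuration
#'
#' @param fill_holes fill interior holes before measuring (default `TRUE`;
#'   `FALSE` keeps the Area-excludes-holes semantics).
#' @param min_area_px components smaller than this are rejected as
#'   segmentation debris (moments and the outline are unreliable below
#'   ~50 px).
#' @param feret_step_deg angular step for mean caliper sampling (degrees).
#' @param diameter_step_deg angular step for centroid diameters (degrees);
#'   2 degrees is the classical convention.
#' @param smooth_window outline smoothing half-width, see [trace_outline()].
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(fill_holes = TRUE, min_area_px = 50L,
                            feret_step_deg = 1, diameter_step_deg = 2,
                            smooth_window = 1L) {
  structure(list(fill_holes = fill_holes,
                 min_area_px = as.integer(min_area_px),
                 feret_step_deg = feret_step_deg,
                 diameter_step_deg = diameter_step_deg,
                 smooth_window = as.integer(smooth_window)),
            class = "geometry_config")
}

feature_names <- function() {
  c("angle", "area", "area_polygon", "area_box", "aspect", "axis_major",
    "axis_minor", "box_height", "box_width", "box_xy", "centre_x", "centre_y",
    "diameter_max", "diameter_mean", "diameter_min", "feret_max", "feret_mean",
    "feret_min", "fractal_dimension", "perimeter", "perimeter_convex",
    "perimeter_ellipse", "perimeter_ratio", "radius_max", "radius_min",
    "radius_ratio", "roundness", "size_length", "size_width")
}

shape_centroid <- function(shape) {
  c(x = mean(shape$pixels[, "col"]), y = mean(shape$pixels[, "row"]))
}

#' Pixel area, polygon area and outline perimeter
#'
#' `area` is the filled pixel count (holes included or excluded depending on
#' how the [cell_shape()] was built); `area_polygon` is the shoelace area of
#' the traced outline; `perimeter` is the outline polygon length.
#'
#' @param shape a [cell_shape()].
#' @return named list `area`, `area_polygon`, `perimeter` (px units).
#' @export
area_and_perimeter <- function(shape) {
  o <- shape$outline
  list(area = nrow(shape$pixels) * shape$pixel_size^2,
       area_polygon = abs(poly_signed_area(o$x, o$y)) * shape$pixel_size^2,
       perimeter = poly_perimeter(o$x, o$y) * shape$pixel_size)
}

#' Equivalent-ellipse axes and orientation
#'
#' The ellipse with the same first and second central moments as the filled
#' pixel set. Axis lengths are `4 * sqrt(eigenvalue)` so a solid ellipse
#' returns its own axis lengths. The angle is measured between the major axis
#' and the image vertical, clockwise positive, in `[0, 180)` degrees.
#'
#' @param shape a [cell_shape()].
#' @return named list `axis_major`, `axis_minor` (px), `angle` (degrees).
#' @export
equivalent_ellipse <- function(shape) {
  px <- shape$pixels[, "col"]
  py <- shape$pixels[, "row"]
  if (length(px) < 5L) {
    stop("equivalent ellipse needs at least 5 pixels")
  }
  mxx <- mean((px - mean(px))^2)
  myy <- mean((py - mean(py))^2)
  mxy <- mean((px - mean(px)) * (py - mean(py)))
  e <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L), symmetric = TRUE)
  major <- 4 * sqrt(max(e$values[1L], 0))
  minor <- 4 * sqrt(max(e$values[2L], 0))
  if (minor < 1) {
    warning("degenerate pixel set: axis_minor floored at 1 px")
    minor <- 1
  }
  v <- e$vectors[, 1L]                       # (x, y) direction of major axis
  phi <- atan2(v[2L], v[1L]) * 180 / pi      # from x-axis, y-down frame
  angle <- (phi + 90) %% 180                 # from vertical, [0, 180)
  list(axis_major = major * shape$pixel_size,
       axis_minor = minor * shape$pixel_size,
       angle = angle,
       major_dir = v)
}

#' Centroid diameters at fixed angular intervals
#'
#' For each angle the diameter is the total chord length of the outline along
#' the line through the pixel centroid at that angle (segments are summed when
#' the line exits and re-enters a concave shape). Angles whose line misses the
#' polygon contribute nothing and are excluded from the mean.
#'
#' @param shape a [cell_shape()].
#' @param angular_step sampling step in degrees over `[0, 180)`.
#' @return named list `diameter_max`, `diameter_mean`, `diameter_min` plus
#'   `n_missed` (angles excluded).
#' @export
centroid_diameters <- function(shape, angular_step = 2) {
  cen <- shape_centroid(shape)
  o <- shape$outline
  thetas <- seq(0, 180 - 1e-9, by = angular_step) * pi / 180
  d <- vapply(thetas, function(th) {
    line_polygon_chord(cen["x"], cen["y"], th, o$x, o$y)
  }, numeric(1L))
  miss <- is.na(d)
  d <- d[!miss]
  if (length(d) == 0L) {
    stop("centroid lies outside the shape at every sampled angle")
  }
  list(diameter_max = max(d) * shape$pixel_size,
       diameter_mean = mean(d) * shape$pixel_size,
       diameter_min = min(d) * shape$pixel_size,
       n_missed = sum(miss))
}

#' Feret (caliper) diameters
#'
#' The caliper width at an angle is the distance between the two parallel
#' supporting lines of the convex hull at that orientation. `feret_max` is
#' computed exactly as the maximum pairwise hull-vertex distance and
#' `feret_min` exactly by rotating calipers over hull edges; `feret_mean`
#' averages sampled widths over `[0, 180)`. `size_length` / `size_width` are
#' the calipers along and perpendicular to the equivalent-ellipse major axis.
#'
#' @param shape a [cell_shape()].
#' @param angular_step sampling step in degrees for the mean caliper.
#' @return named list `feret_max`, `feret_mean`, `feret_min`, `size_length`,
#'   `size_width`.
#' @export
feret_diameters <- function(shape, angular_step = 1) {
  h <- convex_hull(shape$outline$x, shape$outline$y)
  n <- length(h$x)
  # exact max: hull diameter
  dmat <- outer(h$x, h$x, "-")^2 + outer(h$y, h$y, "-")^2
  fmax <- sqrt(max(dmat))
  # exact min width: for each hull edge, the farthest vertex distance
  if (n >= 3L) {
    x2 <- c(h$x[-1L], h$x[1L])
    y2 <- c(h$y[-1L], h$y[1L])
    ex <- x2 - h$x
    ey <- y2 - h$y
    el <- sqrt(ex^2 + ey^2)
    ok <- el > 0
    widths <- vapply(which(ok), function(i) {
      max(abs((h$x - h$x[i]) * ey[i] - (h$y - h$y[i]) * ex[i])) / el[i]
    }, numeric(1L))
    fmin <- min(widths)
  } else {
    fmin <- 0
  }
  thetas <- seq(0, 180 - 1e-9, by = angular_step) * pi / 180
  proj <- outer(h$x, cos(thetas)) + outer(h$y, sin(thetas))
  sampled <- apply(proj, 2L, function(p) max(p) - min(p))
  ee <- equivalent_ellipse(shape)
  v <- ee$major_dir
  pl <- h$x * v[1L] + h$y * v[2L]
  pw <- -h$x * v[2L] + h$y * v[1L]
  ps <- shape$pixel_size
  list(feret_max = fmax * ps,
       feret_mean = mean(sampled) * ps,
       feret_min = fmin * ps,
       size_length = (max(pl) - min(pl)) * ps,
       size_width = (max(pw) - min(pw)) * ps)
}

#' Centroid-to-outline radii
#'
#' `radius_max` is the largest distance from the pixel centroid to the
#' outline (attained at a vertex); `radius_min` the smallest distance to any
#' outline edge; `radius_ratio` their ratio.
#'
#' @param shape a [cell_shape()].
#' @return named list `radius_max`, `radius_min`, `radius_ratio`.
#' @export
shape_radii <- function(shape) {
  cen <- shape_centroid(shape)
  o <- shape$outline
  rmax <- sqrt(max((o$x - cen["x"])^2 + (o$y - cen["y"])^2))
  rmin <- point_to_polygon_dist(cen["x"], cen["y"], o$x, o$y)
  if (rmin < 0.5) {
    warning("radius_min below half a pixel; floored at 0.5 px")
    rmin <- 0.5
  }
  list(radius_max = rmax * shape$pixel_size,
       radius_min = rmin * shape$pixel_size,
       radius_ratio = rmax / rmin)
}

# Perimeter of an ellipse with semi-axes a >= b via numeric quadrature of the
# complete elliptic integral of the second kind (relative error < 1e-9).
ellipse_perimeter <- function(a, b) {
  if (a < b) {
    tmp <- a; a <- b; b <- tmp
  }
  if (a == 0) {
    return(0)
  }
  e2 <- 1 - (b / a)^2
  4 * a * stats::integrate(function(t) sqrt(1 - e2 * sin(t)^2),
                           0, pi / 2, rel.tol = 1e-10)$value
}

#' Convex and equivalent-ellipse perimeters
#'
#' @param shape a [cell_shape()].
#' @return named list `perimeter_convex` (hull polygon length),
#'   `perimeter_ellipse` (equivalent-ellipse circumference, elliptic-integral
#'   quadrature) and `perimeter_ratio` (convex / outline perimeter).
#' @export
convex_and_ellipse_perimeters <- function(shape) {
  h <- convex_hull(shape$outline$x, shape$outline$y)
  pc <- poly_perimeter(h$x, h$y)
  ee <- equivalent_ellipse(shape)
  pe <- ellipse_perimeter(ee$axis_major / 2, ee$axis_minor / 2)
  p <- poly_perimeter(shape$outline$x, shape$outline$y)
  list(perimeter_convex = pc * shape$pixel_size,
       perimeter_ellipse = pe,
       perimeter_ratio = pc / p)
}

#' Box-counting fractal dimension of an outline
#'
#' The outline is scaled so its long side spans at least `grid_side` boxes,
#' densely sampled along its edges, and occupied boxes are counted at dyadic
#' box sizes 2, 4, ..., `grid_side`/4. The estimate is the least-squares slope
#' of log(count) against log(1/size), clamped to `[1, 2]`.
#'
#' @param outline closed polygon (list `x`, `y`).
#' @param grid_side minimum rasterization grid side (px).
#' @return fractal dimension in `[1, 2]`.
#' @export
fractal_dimension <- function(outline, grid_side = 128L) {
  x <- outline$x
  y <- outline$y
  ext <- max(diff(range(x)), diff(range(y)))
  if (ext <= 0) {
    stop("shape too small for fractal estimate")
  }
  s <- max(1, grid_side / ext)
  x <- (x - min(x)) * s
  y <- (y - min(y)) * s
  side <- max(grid_side, ceiling(max(max(x), max(y))))
  sizes <- 2^(1:floor(log2(side / 4)))
  if (length(sizes) < 4L) {
    stop("shape too small for fractal estimate")
  }
  # dense samples along each edge, step ~0.5 boxes at the finest scale
  x2 <- c(x[-1L], x[1L])
  y2 <- c(y[-1L], y[1L])
  len <- sqrt((x2 - x)^2 + (y2 - y)^2)
  nseg <- pmax(1L, ceiling(len / 0.5))
  t <- unlist(lapply(nseg, function(k) (seq_len(k) - 1) / k))
  i <- rep(seq_along(x), nseg)
  sx <- x[i] + t * (x2[i] - x[i])
  sy <- y[i] + t * (y2[i] - y[i])
  counts <- vapply(sizes, function(b) {
    length(unique(floor(sx / b) * 1e6 + floor(sy / b)))
  }, numeric(1L))
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  min(2, max(1, unname(coef(fit)[2L])))
}

#' Compute all shape descriptors for one cell
#'
#' Populates every descriptor field (the 28 classical parameters plus plain
#' perimeter) from a [cell_shape()]. Deterministic for a fixed mask and
#' configuration.
#'
#' @param shape a [cell_shape()].
#' @param config a [geometry_config()].
#' @return one-row `data.frame` with the columns of `feature_names()`.
#' @export
shape_features <- function(shape, config = geometry_config()) {
  res <- try({
    ap <- area_and_perimeter(shape)
    if (nrow(shape$pixels) < config$min_area_px) {
      stop(sprintf("component of %d px below min_area_px = %d",
                   nrow(shape$pixels), config$min_area_px))
    }
    ee <- equivalent_ellipse(shape)
    cd <- centroid_diameters(shape, angular_step = config$diameter_step_deg)
    fd <- feret_diameters(shape, angular_step = config$feret_step_deg)
    ra <- shape_radii(shape)
    cp <- convex_and_ellipse_perimeters(shape)
    fr <- fractal_dimension(shape$outline)
    cen <- shape_centroid(shape)
    o <- shape$outline
    bw <- diff(range(o$x)) * shape$pixel_size
    bh <- diff(range(o$y)) * shape$pixel_size
    data.frame(angle = ee$angle,
               area = ap$area,
               area_polygon = ap$area_polygon,
               area_box = ap$area / (bw * bh),
               aspect = ee$axis_major / ee$axis_minor,
               axis_major = ee$axis_major,
               axis_minor = ee$axis_minor,
               box_height = bh,
               box_width = bw,
               box_xy = bw / bh,
               centre_x = unname(cen["x"]) * shape$pixel_size,
               centre_y = unname(cen["y"]) * shape$pixel_size,
               diameter_max = cd$diameter_max,
               diameter_mean = cd$diameter_mean,
               diameter_min = cd$diameter_min,
               feret_max = fd$feret_max,
               feret_mean = fd$feret_mean,
               feret_min = fd$feret_min,
               fractal_dimension = fr,
               perimeter = ap$perimeter,
               perimeter_convex = cp$perimeter_convex,
               perimeter_ellipse = cp$perimeter_ellipse,
               perimeter_ratio = cp$perimeter_ratio,
               radius_max = ra$radius_max,
               radius_min = ra$radius_min,
               radius_ratio = ra$radius_ratio,
               roundness = ap$perimeter^2 / (4 * pi * ap$area),
               size_length = fd$size_length,
               size_width = fd$size_width)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    stop(sprintf("cell %d: %s", shape$label,
                 conditionMessage(attr(res, "condition"))))
  }
  res
}
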