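test_that("trace_outline handles the smallest mask and errors on bad input", {
  m <- matrix(0, 3, 3)
  m[2, 2] <- 1
  p <- trace_outline(m, smooth_window = 0L)
  expect_length(p$x, 4L)
  # the 4-vertex contour encloses the pixel centre (1, 1)
  expect_true(min(p$x) < 1 && max(p$x) > 1)
  expect_true(min(p$y) < 1 && max(p$y) > 1)
  expect_gt(abs(0.5 * sum(p$x * c(p$y[-1], p$y[1]) -
                          c(p$x[-1], p$x[1]) * p$y)), 0)
  expect_error(trace_outline(matrix(0, 4, 4)), "no foreground")
  m2 <- matrix(0, 6, 6)
  m2[2, 2] <- 1
  m2[5, 5] <- 1
  expect_error(trace_outline(m2), "not a single cell")
})

test_that("outline polygon area tracks pixel-count area on large components", {
  sq <- rect_mask(50, 50)
  p <- trace_outline(sq)
  a <- abs(0.5 * sum(p$x * c(p$y[-1], p$y[1]) - c(p$x[-1], p$x[1]) * p$y))
  expect_equal(a, 2500, tolerance = 0.015)
  d <- disc_mask(50)
  pd <- trace_outline(d)
  ad <- abs(0.5 * sum(pd$x * c(pd$y[-1], pd$y[1]) -
                      c(pd$x[-1], pd$x[1]) * pd$y))
  expect_equal(ad, pi * 50^2, tolerance = 0.015)
})

test_that("area and perimeter match closed forms, holes honoured", {
  s <- cell_shape(rect_mask(25, 100))
  ap <- area_and_perimeter(s)
  expect_equal(ap$area, 2500)
  expect_equal(ap$perimeter, 250, tolerance = 0.02)
  sd <- cell_shape(disc_mask(50))
  apd <- area_and_perimeter(sd)
  expect_equal(apd$perimeter, 2 * pi * 50, tolerance = 0.03)
  holed <- rect_mask(20, 20)
  holed[12:13, 12:13] <- 0
  s_off <- cell_shape(holed, fill_holes = FALSE)
  s_on <- cell_shape(holed, fill_holes = TRUE)
  expect_equal(area_and_perimeter(s_on)$area -
               area_and_perimeter(s_off)$area, 4)
})

test_that("equivalent ellipse reproduces known shapes and the moment oracle", {
  se <- cell_shape(ellipse_mask(40, 20))
  ee <- equivalent_ellipse(se)
  expect_equal(ee$axis_major, 80, tolerance = 0.02)
  expect_equal(ee$axis_minor, 40, tolerance = 0.02)
  expect_equal(ee$angle, 90, tolerance = 1e-6)
  sd <- cell_shape(disc_mask(30))
  ed <- equivalent_ellipse(sd)
  expect_equal(ed$axis_major, 60, tolerance = 0.02)
  expect_equal(ed$axis_minor, 60, tolerance = 0.02)
  # brute-force pixel-moment oracle on an asymmetric shape
  sb <- cell_shape(random_blob_mask(3))
  eb <- equivalent_ellipse(sb)
  or <- brute_moment_axes(sb$pixels)
  expect_equal(eb$axis_major, unname(or["major"]), tolerance = 1e-9)
  expect_equal(eb$axis_minor, unname(or["minor"]), tolerance = 1e-9)
  # vertical rectangle: major axis along the vertical -> angle 0
  sv <- cell_shape(rect_mask(100, 25))
  expect_equal(equivalent_ellipse(sv)$angle, 0, tolerance = 1e-6)
})

test_that("centroid diameters match disc and rectangle closed forms", {
  sd <- cell_shape(disc_mask(50))
  cd <- centroid_diameters(sd)
  expect_equal(cd$diameter_max, 100, tolerance = 0.02)
  expect_equal(cd$diameter_mean, 100, tolerance = 0.02)
  expect_equal(cd$diameter_min, 100, tolerance = 0.02)
  sr <- cell_shape(rect_mask(25, 100))
  cr <- centroid_diameters(sr)
  expect_equal(cr$diameter_max, sqrt(100^2 + 25^2), tolerance = 0.02)
  expect_equal(cr$diameter_min, 25, tolerance = 0.02)
})

test_that("feret calipers match closed forms and dominate centroid chords", {
  sd <- cell_shape(disc_mask(50))
  fd <- feret_diameters(sd)
  expect_equal(fd$feret_max, 100, tolerance = 0.02)
  expect_equal(fd$feret_min, 100, tolerance = 0.02)
  sr <- cell_shape(rect_mask(25, 100))
  fr <- feret_diameters(sr)
  expect_equal(fr$feret_max, sqrt(100^2 + 25^2), tolerance = 0.02)
  expect_equal(fr$feret_min, 25, tolerance = 0.02)
  expect_equal(fr$size_length, 100, tolerance = 0.02)
  expect_equal(fr$size_width, 25, tolerance = 0.02)
  for (seed in c(1, 2, 5)) {
    s <- cell_shape(random_blob_mask(seed))
    expect_gte(feret_diameters(s)$feret_max,
               centroid_diameters(s)$diameter_max - 1e-9)
  }
})

test_that("centroid radii match disc, ellipse and rectangle geometry", {
  expect_equal(shape_radii(cell_shape(disc_mask(50)))$radius_ratio, 1,
               tolerance = 0.02)
  expect_equal(shape_radii(cell_shape(ellipse_mask(40, 20)))$radius_ratio, 2,
               tolerance = 0.03)
  rr <- shape_radii(cell_shape(rect_mask(25, 100)))
  expect_equal(rr$radius_max, sqrt(50^2 + 12.5^2), tolerance = 0.03)
  expect_equal(rr$radius_min, 12.5, tolerance = 0.03)
  expect_equal(rr$radius_ratio, sqrt(50^2 + 12.5^2) / 12.5, tolerance = 0.03)
  # point-to-segment oracle on an irregular shape
  s <- cell_shape(random_blob_mask(7))
  cx <- mean(s$pixels[, "col"])
  cy <- mean(s$pixels[, "row"])
  o <- s$outline
  n <- length(o$x)
  dists <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    seg_dist(cx, cy, o$x[i], o$y[i], o$x[j], o$y[j])
  }, numeric(1L))
  expect_equal(shape_radii(s)$radius_min, min(dists), tolerance = 1e-9)
})

test_that("convex and ellipse perimeters behave and match quadrature", {
  sd <- cell_shape(disc_mask(50))
  cp <- convex_and_ellipse_perimeters(sd)
  expect_equal(cp$perimeter_ratio, 1, tolerance = 0.02)
  se <- cell_shape(ellipse_mask(40, 20))
  ce <- convex_and_ellipse_perimeters(se)
  expect_equal(ce$perimeter_ellipse, 193.77, tolerance = 0.01)
  # independent dense-polygon oracle for the elliptic integral
  ee <- equivalent_ellipse(se)
  expect_equal(ce$perimeter_ellipse,
               dense_ellipse_perimeter(ee$axis_major / 2, ee$axis_minor / 2),
               tolerance = 1e-6)
  # concave blob: hull shorter than outline
  sb <- cell_shape(random_blob_mask(11, amp = 0.4))
  expect_lt(convex_and_ellipse_perimeters(sb)$perimeter_ratio, 1)
})

test_that("fractal dimension is ~1 for smooth outlines and rises with noise", {
  expect_equal(fractal_dimension(cell_shape(disc_mask(100))$outline), 1,
               tolerance = 0.1)
  expect_equal(fractal_dimension(cell_shape(rect_mask(60, 120))$outline), 1,
               tolerance = 0.1)
  set.seed(99)
  t <- seq(0, 2 * pi, length.out = 241L)[-241L]
  smooth <- list(x = 100 * cos(t), y = 100 * sin(t))
  noisy <- list(x = smooth$x + runif(240L, -5, 5),
                y = smooth$y + runif(240L, -5, 5))
  expect_gt(fractal_dimension(noisy), fractal_dimension(smooth))
  expect_error(fractal_dimension(list(x = c(0, 4, 4, 0), y = c(0, 0, 4, 4)),
                                 grid_side = 16L),
               "too small for fractal")
})

test_that("composite ratios match the rectangle and disc closed forms", {
  f <- shape_features(cell_shape(rect_mask(25, 100)))
  expect_equal(f$roundness, 250^2 / (4 * pi * 2500), tolerance = 0.03)
  expect_equal(f$box_xy, 4, tolerance = 0.01)
  expect_equal(f$area_box, 1, tolerance = 0.01)
  fd <- shape_features(cell_shape(disc_mask(50)))
  expect_equal(fd$roundness, 1, tolerance = 0.05)
  expect_equal(fd$aspect, 1, tolerance = 0.02)
  expect_equal(fd$area_box, pi / 4, tolerance = 0.02)
})

test_that("shape_features is deterministic and complete", {
  s <- cell_shape(random_blob_mask(13))
  f1 <- shape_features(s)
  f2 <- shape_features(s)
  expect_identical(f1, f2)
  expect_named(f1, cellmorph:::feature_names())
  expect_false(anyNA(f1))
})

test_that("a 90-degree rotation preserves invariant descriptors, swaps box", {
  m <- random_blob_mask(17, amp = 0.3)
  f <- shape_features(cell_shape(m))
  m90 <- t(m)[, nrow(m):1]                    # exact 90-degree rotation
  f90 <- shape_features(cell_shape(m90))
  for (d in c("area", "perimeter", "roundness", "aspect", "radius_ratio")) {
    expect_equal(f90[[d]], f[[d]], tolerance = 0.02, label = d)
  }
  expect_equal(f90$box_xy, 1 / f$box_xy, tolerance = 0.02)
})

test_that("small components are rejected as debris", {
  tiny <- matrix(0, 10, 10)
  tiny[4:6, 4:6] <- 1
  expect_error(shape_features(cell_shape(tiny)), "min_area_px")
})
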