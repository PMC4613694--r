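#' Synthetic scene configuration
#'
#' Parameters of the synthetic "micrograph" generator: two groups of label
#' images populated with non-overlapping cell silhouettes drawn from two
#' shape families — compact, gently lobed "cobblestone" epithelial cells and
#' elongated, tapered, randomly bent "spindle" mesenchymal cells — at uniform
#' random orientation. Both families occur in both groups; only the mixture
#' fraction differs, mirroring how EMT shifts a population rather than
#' switching every cell.
#'
#' @param n_images_per_group images per group (default 30, a typical
#'   experiment size of this kind).
#' @param cells_per_image cells placed per image.
#' @param image_size `(height, width)` px.
#' @param epithelial_fraction named vector: probability that a cell is
#'   epithelial in the `untreated` and `treated` group.
#' @param size_meanlog,size_sdlog lognormal parameters of the equivalent
#'   radius in px (median `exp(size_meanlog)`).
#' @param epi_aspect_meanlog,epi_aspect_sdlog lognormal aspect-ratio
#'   parameters of epithelial cells (median ~1.2, tail reaching ~2: real
#'   epithelial sheets contain moderately elongated cells).
#' @param mes_aspect_meanlog,mes_aspect_sdlog lognormal aspect-ratio
#'   parameters of mesenchymal cells (median ~4).
#' @param mes_min_bend,mes_max_bend range of the total bending angle of a
#'   spindle's centreline in radians (drawn uniformly); mesenchymal cells are
#'   rarely straight rods, and bending lowers the moment-based aspect of a
#'   spindle without changing its perimeter-area relation.
#' @param boundary_noise_amp per-vertex jitter amplitude in px.
#' @param seed integer seed fixing the entire scene set.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(n_images_per_group = 30L,
                         cells_per_image = 40L,
                         image_size = c(512L, 512L),
                         epithelial_fraction = c(untreated = 0.85,
                                                 treated = 0.30),
                         size_meanlog = log(12),
                         size_sdlog = 0.25,
                         epi_aspect_meanlog = log(1.2),
                         epi_aspect_sdlog = 0.35,
                         mes_aspect_meanlog = log(4),
                         mes_aspect_sdlog = 0.25,
                         mes_min_bend = 1.2,
                         mes_max_bend = 3.0,
                         boundary_noise_amp = 0.8,
                         seed = 1L) {
  stopifnot(all(epithelial_fraction >= 0), all(epithelial_fraction <= 1),
            all(c("untreated", "treated") %in% names(epithelial_fraction)))
  structure(list(n_images_per_group = as.integer(n_images_per_group),
                 cells_per_image = as.integer(cells_per_image),
                 image_size = as.integer(image_size),
                 epithelial_fraction = epithelial_fraction,
                 size_meanlog = size_meanlog,
                 size_sdlog = size_sdlog,
                 epi_aspect_meanlog = epi_aspect_meanlog,
                 epi_aspect_sdlog = epi_aspect_sdlog,
                 mes_aspect_meanlog = mes_aspect_meanlog,
                 mes_aspect_sdlog = mes_aspect_sdlog,
                 mes_min_bend = mes_min_bend,
                 mes_max_bend = mes_max_bend,
                 boundary_noise_amp = boundary_noise_amp,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Boundary polygon of one synthetic cell in local coordinates, centred near
# the origin. Consumes the current RNG stream.
make_cell_polygon <- function(class, config) {
  R <- rlnorm(1L, config$size_meanlog, config$size_sdlog)
  if (class == "epithelial") {
    aspect <- max(1, rlnorm(1L, config$epi_aspect_meanlog,
                            config$epi_aspect_sdlog))
    a <- R * sqrt(aspect)
    b <- R / sqrt(aspect)
    n <- runif(1L, 2, 3)                     # superellipse exponent
    t <- seq(0, 2 * pi, length.out = 121L)[-121L]
    x <- a * sign(cos(t)) * abs(cos(t))^(2 / n)
    y <- b * sign(sin(t)) * abs(sin(t))^(2 / n)
    # smooth low-order radial lobes
    k <- 2:5
    ck <- rnorm(4L, 0, 0.03)
    ph <- runif(4L, 0, 2 * pi)
    rho <- 1 + as.vector(cos(outer(t, k) + rep(ph, each = length(t))) %*% ck)
    x <- x * rho
    y <- y * rho
    bend <- 0
  } else {
    aspect <- max(1.5, rlnorm(1L, config$mes_aspect_meanlog,
                              config$mes_aspect_sdlog))
    a <- R * sqrt(aspect)
    b <- R / sqrt(aspect)
    p <- runif(1L, 0.5, 0.9)                 # taper exponent (pointed ends)
    u <- seq(0, pi, length.out = 61L)
    xs <- a * cos(u)
    w <- b * sin(u)^(2 * p)
    x <- c(xs, rev(xs)[-c(1L, 61L)])
    y <- c(w, -rev(w)[-c(1L, 61L)])
    bend <- runif(1L, config$mes_min_bend, config$mes_max_bend)
  }
  if (bend > 0.05) {                         # bend centreline into an arc
    rb <- 2 * max(abs(x)) / bend
    x0 <- x
    x <- (rb - y) * sin(x0 / rb)
    y <- rb - (rb - y) * cos(x0 / rb)
    y <- y - mean(range(y))
  }
  theta <- runif(1L, 0, pi)                  # uniform random orientation
  xr <- x * cos(theta) - y * sin(theta)
  yr <- x * sin(theta) + y * cos(theta)
  amp <- config$boundary_noise_amp
  if (amp > 0) {
    xr <- xr + runif(length(xr), -amp / 2, amp / 2)
    yr <- yr + runif(length(yr), -amp / 2, amp / 2)
  }
  list(x = xr, y = yr)
}

#' Generate one synthetic cell
#'
#' Draws a cell silhouette from the epithelial ("cobblestone": compact
#' superellipse with smooth radial lobes) or mesenchymal ("spindle":
#' elongated, tapered, randomly bent) family, at uniform random orientation,
#' rasterizes it and returns it as a [cell_shape()]. Uses the current RNG
#' stream; wrap in `set.seed()` for reproducibility.
#'
#' @param class `"epithelial"` or `"mesenchymal"`.
#' @param config a [scene_config()].
#' @param label label id for the resulting shape.
#' @return a [cell_shape()] with attributes `class` (ground-truth family) and
#'   `polygon` (the generating boundary).
#' @export
make_cell <- function(class = c("epithelial", "mesenchymal"),
                      config = scene_config(), label = 1L) {
  class <- match.arg(class)
  poly <- make_cell_polygon(class, config)
  m <- rasterize_polygon(poly$x, poly$y)
  lab <- label_components(m)
  if (max(lab) > 1L) {                       # keep the largest fragment
    m <- lab == which.max(tabulate(lab[lab > 0L]))
  }
  shape <- cell_shape(m, label = label, fill_holes = TRUE)
  attr(shape, "class_truth") <- class
  attr(shape, "polygon") <- poly
  shape
}

#' Generate a full synthetic scene set
#'
#' Produces `n_images_per_group` labelled images for each of the two groups.
#' The untreated group is epithelial-dominated and the treated group
#' mesenchymal-dominated (per `epithelial_fraction`); cells never overlap and
#' keep a 1-px separation so labels stay 8-disconnected. The whole set is a
#' deterministic function of `config$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param config a [scene_config()].
#' @return list of class `scene_set`: `images` (list of
#'   [segmented_image()]), `truth` (`data.frame` with `image_id`, `cell_id`,
#'   `group_label`, `class`, `area_px`), `config`.
#' @export
make_scene_set <- function(config = scene_config()) {
  with_local_seed(config$seed, {
    images <- list()
    truth <- list()
    h <- config$image_size[1L]
    w <- config$image_size[2L]
    for (group in c("untreated", "treated")) {
      p_epi <- config$epithelial_fraction[[group]]
      for (i in seq_len(config$n_images_per_group)) {
        image_id <- sprintf("%s_%02d", group, i)
        raster <- matrix(0L, h, w)
        occupied <- matrix(FALSE, h, w)
        img_truth <- list()
        for (j in seq_len(config$cells_per_image)) {
          class <- if (runif(1L) < p_epi) "epithelial" else "mesenchymal"
          cell <- make_cell(class, config, label = j)
          m <- cell$mask
          ch <- nrow(m)
          cw <- ncol(m)
          if (ch > h - 2L || cw > w - 2L) {
            stop("cell larger than image; lower the size distribution ",
                 "or enlarge image_size")
          }
          placed <- FALSE
          for (attempt in seq_len(1000L)) {
            r0 <- sample.int(h - ch - 1L, 1L)       # 1-px clear border
            c0 <- sample.int(w - cw - 1L, 1L)
            sub <- occupied[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L)]
            if (!any(sub & m)) {
              idx <- which(m)
              rows <- ((idx - 1L) %% ch) + r0
              cols <- ((idx - 1L) %/% ch) + c0
              raster[cbind(rows, cols)] <- j
              # block the 8-neighbourhood so neighbouring cells stay separate
              for (dr in -1L:1L) for (dc in -1L:1L) {
                rs <- pmin(pmax(rows + dr, 1L), h)
                cs <- pmin(pmax(cols + dc, 1L), w)
                occupied[cbind(rs, cs)] <- TRUE
              }
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            stop("could not place cell ", j, " in ", image_id,
                 " after 1000 attempts; lower cells_per_image or cell size")
          }
          img_truth[[j]] <-
            data.frame(image_id = image_id, cell_id = j,
                       group_label = group, class = class,
                       area_px = sum(m),
                       first_row = rows[1L], first_col = cols[1L],
                       stringsAsFactors = FALSE)
        }
        seg <- segmented_image(raster, group_label = group,
                               image_id = image_id)
        if (length(img_truth) > 0L) {
          tr <- do.call(rbind, img_truth)
          # segmented_image relabels in scan order; recover the new ids
          tr$cell_id <- seg$raster[cbind(tr$first_row, tr$first_col)]
          tr$first_row <- NULL
          tr$first_col <- NULL
          truth[[length(truth) + 1L]] <- tr
        }
        images[[image_id]] <- seg
      }
    }
    truth_df <- if (length(truth) > 0L) {
      do.call(rbind, truth)
    } else {
      data.frame(image_id = character(0), cell_id = integer(0),
                 group_label = character(0), class = character(0),
                 area_px = integer(0), stringsAsFactors = FALSE)
    }
    structure(list(images = images, truth = truth_df, config = config),
              class = "scene_set")
  })
}

#' @export
print.scene_set <- function(x, ...) {
  cat(sprintf("<scene_set> %d images, %d cells (seed %d)\n",
              length(x$images), nrow(x$truth), x$config$seed))
  invisible(x)
}
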