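#' Systematic sampling grid specification
#'
#' A regular point lattice overlaid on the image; cells hit by at least one
#' lattice point are selected for measurement, which makes selection
#' probability proportional to cell area (systematic point-count sampling).
#'
#' @param spacing lattice period in px (>= 2).
#' @param offset `(dx, dy)` lattice origin in px, each in `[0, spacing)`.
#' @param jitter_seed optional integer; when set, a single uniform random
#'   offset in `[0, spacing)^2` replaces `offset` (unbiased systematic
#'   sampling), reproducibly for a fixed seed.
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(spacing, offset = c(0, 0), jitter_seed = NULL) {
  if (spacing < 2) {
    stop("grid spacing must be >= 2 px")
  }
  if (any(offset < 0) || any(offset >= spacing)) {
    stop("offset components must lie in [0, spacing)")
  }
  structure(list(spacing = spacing, offset = offset,
                 jitter_seed = jitter_seed),
            class = "grid_spec")
}

#' Enumerate grid points inside an image
#'
#' @param image_shape `(height, width)` in px.
#' @param grid a [grid_spec()].
#' @return two-column matrix of 0-based `(x, y)` lattice points inside the
#'   image (`0 <= x <= width - 1`, `0 <= y <= height - 1`).
#' @export
grid_points <- function(image_shape, grid) {
  off <- grid$offset
  if (!is.null(grid$jitter_seed)) {
    off <- with_local_seed(grid$jitter_seed, runif(2L, 0, grid$spacing))
  }
  h <- image_shape[1L]
  w <- image_shape[2L]
  xs <- seq(off[1L], w - 1, by = grid$spacing)
  ys <- seq(off[2L], h - 1, by = grid$spacing)
  as.matrix(expand.grid(x = xs, y = ys))
}

#' Select cells hit by grid points
#'
#' @param seg a [segmented_image()].
#' @param points matrix of `(x, y)` points as from [grid_points()]; fractional
#'   coordinates are assigned to the nearest pixel centre.
#' @return sorted integer vector of cell labels containing at least one point.
#' @export
select_cells <- function(seg, points) {
  if (nrow(points) == 0L) {
    return(integer(0L))
  }
  r <- round(points[, 2L]) + 1L
  c <- round(points[, 1L]) + 1L
  keep <- r >= 1L & r <= nrow(seg$raster) & c >= 1L & c <= ncol(seg$raster)
  ids <- seg$raster[cbind(r[keep], c[keep])]
  sort(unique(ids[ids > 0L]))
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
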