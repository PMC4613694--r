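#' Trace the sub-pixel outline of a single-cell binary mask
#'
#' Runs marching squares (via [grDevices::contourLines()]) at level 0.5 on the
#' zero-padded mask, keeps the outermost contour, applies a light 3-point
#' circular moving average to suppress the half-pixel staircase, and returns
#' the vertices in counter-clockwise order (positive shoelace area in the
#' `x = col`, `y = row` frame).
#'
#' @param mask logical or 0/1 matrix containing exactly one 8-connected
#'   foreground component.
#' @param smooth_window half-width of the circular moving-average smoother in
#'   vertices; `0` disables smoothing.
#' @return list with numeric `x` and `y`: a simple closed polygon (closing
#'   edge implicit) in 0-based pixel coordinates.
#' @examples
#' m <- matrix(0, 20, 20); m[5:15, 5:15] <- 1
#' p <- trace_outline(m)
#' abs(0.5 * sum(p$x * c(p$y[-1], p$y[1]) - c(p$x[-1], p$x[1]) * p$y)) # ~121
#' @export
trace_outline <- function(mask, smooth_window = 1L) {
  mask <- mask != 0
  if (!any(mask)) {
    stop("no foreground")
  }
  lab <- label_components(mask)
  if (max(lab) > 1L) {
    stop("not a single cell")
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1
  # contourLines: first z index -> its x; rows are our y, columns our x
  cl <- grDevices::contourLines(x = seq_len(nr + 2L) - 2, # 0-based row coords
                                y = seq_len(nc + 2L) - 2,
                                z = pad, levels = 0.5)
  areas <- vapply(cl, function(p) abs(poly_signed_area(p$y, p$x)), numeric(1L))
  outer <- cl[[which.max(areas)]]
  n <- length(outer$x)
  p <- list(x = outer$y[-n], y = outer$x[-n])  # drop repeated closing vertex
  p <- smooth_closed_polygon(p$x, p$y, smooth_window)
  ensure_ccw(p)
}

#' Construct a single-cell shape from a binary mask
#'
#' Bundles the filled pixel set, the traced sub-pixel outline and a label id
#' into a `cell_shape` object, the unit every descriptor operates on.
#'
#' @param mask logical or 0/1 matrix with exactly one 8-connected foreground
#'   component (a crop around one cell).
#' @param label positive integer id of the cell.
#' @param offset 0-based `(row, col)` offset of `mask`'s `[1, 1]` within the
#'   source image, so pixel and outline coordinates are reported in image
#'   space.
#' @param fill_holes if `TRUE` (default, matching filled one-hue cell
#'   regions), interior holes are filled before the pixel set is recorded; if
#'   `FALSE` the pixel count excludes holes while the outline remains the
#'   outer contour.
#' @param pixel_size physical length per pixel (default 1).
#' @param smooth_window outline smoothing, see [trace_outline()].
#' @return object of class `cell_shape` with fields `label`, `pixels`
#'   (n x 2 matrix of 0-based `(row, col)`), `outline` (list `x`, `y`),
#'   `mask`, `offset`, `pixel_size`.
#' @export
cell_shape <- function(mask, label = 1L, offset = c(0L, 0L),
                       fill_holes = TRUE, pixel_size = 1,
                       smooth_window = 1L) {
  mask <- mask != 0
  if (!any(mask)) {
    stop("no foreground")
  }
  cb <- crop_bbox(mask)
  m <- cb$mask
  if (fill_holes) {
    m_filled <- fill_mask_holes(m)
  } else {
    m_filled <- m
  }
  out <- trace_outline(m_filled | m, smooth_window = smooth_window)
  idx <- which(m_filled, arr.ind = TRUE)
  r0 <- offset[1L] + cb$r0
  c0 <- offset[2L] + cb$c0
  pixels <- cbind(row = idx[, 1L] - 1L + r0, col = idx[, 2L] - 1L + c0)
  structure(list(label = as.integer(label),
                 pixels = pixels,
                 outline = list(x = out$x + c0, y = out$y + r0),
                 mask = m,
                 offset = c(r0, c0),
                 pixel_size = pixel_size),
            class = "cell_shape")
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf("<cell_shape> label %d: %d px, outline %d vertices\n",
              x$label, nrow(x$pixels), length(x$outline$x)))
  invisible(x)
}
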