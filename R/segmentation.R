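#' Construct a segmented (label) image
#'
#' @param raster integer matrix of cell labels, background = 0. Labels are
#'   relabelled to contiguous 1..k in order of first pixel in row-major
#'   (top-left) scan order.
#' @param group_label `"treated"` or `"untreated"`.
#' @param image_id identifier of the source image.
#' @param source_path optional path the raster came from.
#' @return object of class `segmented_image`; attribute `empty` is `TRUE`
#'   when the image holds no labelled object.
#' @export
segmented_image <- function(raster, group_label = NA_character_,
                            image_id = "image", source_path = NA_character_) {
  raster <- relabel_scan_order(raster)
  obj <- structure(list(raster = raster,
                        group_label = group_label,
                        image_id = image_id,
                        source_path = source_path),
                   class = "segmented_image")
  attr(obj, "empty") <- max(raster) == 0L
  obj
}

#' @export
print.segmented_image <- function(x, ...) {
  cat(sprintf("<segmented_image> %s [%s]: %dx%d px, %d cells\n",
              x$image_id, x$group_label, nrow(x$raster), ncol(x$raster),
              max(x$raster)))
  invisible(x)
}

read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) {
    stop("cannot read image: ", path)
  }
  switch(ext,
         png = png::readPNG(path),
         tif = ,
         tiff = tiff::readTIFF(path),
         jpg = ,
         jpeg = jpeg::readJPEG(path),
         stop("unsupported image format: .", ext))
}

#' Load a two-hue segmentation or label mask from an image file
#'
#' Two-hue mode (both hues supplied) recovers the cells-vs-background
#' semantics of manually outlined images: every pixel is assigned to the
#' nearer of the two declared hues, provided it lies within Euclidean RGB
#' distance 30 (on the 0-255 scale) of one of them — a tolerance that absorbs
#' JPEG compression noise. Cell pixels are then labelled by 8-connected
#' components. Without hues, the file is taken to be a pre-labelled integer
#' mask (grey levels = labels, 0 = background).
#'
#' @param path PNG, TIFF or JPEG file.
#' @param cell_hue,background_hue hex strings like `"FF0000"`, or length-3
#'   RGB vectors on 0-255; both or neither must be given.
#' @param group_label,image_id metadata stored on the result; `image_id`
#'   defaults to the file name.
#' @param tolerance maximum RGB distance to the nearest declared hue.
#' @return a [segmented_image()].
#' @export
load_segmentation <- function(path, cell_hue = NULL, background_hue = NULL,
                              group_label = NA_character_, image_id = NULL,
                              tolerance = 30) {
  img <- read_image_array(path)
  if (is.null(image_id)) {
    image_id <- basename(path)
  }
  if (is.null(cell_hue) != is.null(background_hue)) {
    stop("supply both cell_hue and background_hue, or neither")
  }
  if (is.null(cell_hue)) {
    if (length(dim(img)) == 3L) {
      img <- img[, , 1L]
    }
    v <- round(img * 65535)
    nz <- v[v > 0]
    if (length(nz) > 0L && all(nz %% 257 == 0)) {
      v <- v / 257                       # 8-bit label image
    }
    raster <- round(v)
    storage.mode(raster) <- "integer"
  } else {
    cell_hue <- parse_hue(cell_hue)
    background_hue <- parse_hue(background_hue)
    if (length(dim(img)) == 2L) {
      img <- array(rep(img, 3L), c(dim(img), 3L))
    }
    r <- img[, , 1L] * 255
    g <- img[, , 2L] * 255
    b <- img[, , 3L] * 255
    d_cell <- sqrt((r - cell_hue[1L])^2 + (g - cell_hue[2L])^2 +
                   (b - cell_hue[3L])^2)
    d_bg <- sqrt((r - background_hue[1L])^2 + (g - background_hue[2L])^2 +
                 (b - background_hue[3L])^2)
    stray <- pmin(d_cell, d_bg) > tolerance
    if (any(stray)) {
      hues <- sprintf("%02X%02X%02X", round(r[stray]), round(g[stray]),
                      round(b[stray]))
      tab <- sort(table(hues), decreasing = TRUE)
      stop("image has hues beyond tolerance of the two declared hues: ",
           paste(sprintf("%s (%d px)", names(tab), tab)[
             seq_len(min(5L, length(tab)))], collapse = ", "))
    }
    mask <- d_cell < d_bg
    raster <- label_components(mask)
  }
  segmented_image(raster, group_label = group_label, image_id = image_id,
                  source_path = path)
}

#' Write a segmented image as an 8-bit PNG label mask
#'
#' Grey value = cell label, 0 = background; readable back with
#' [load_segmentation()].
#'
#' @param seg a [segmented_image()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  if (max(seg$raster) > 255L) {
    stop("more than 255 labels cannot be stored in an 8-bit PNG label mask")
  }
  png::writePNG(seg$raster / 255, path)
  invisible(path)
}

parse_hue <- function(h) {
  if (is.character(h)) {
    h <- sub("^#", "", h)
    h <- strtoi(substring(h, c(1L, 3L, 5L), c(2L, 4L, 6L)), 16L)
  }
  as.numeric(h)
}

#' Extract per-cell shapes from a segmented image
#'
#' @param seg a [segmented_image()].
#' @param exclude_border drop cells touching the image border (default
#'   `TRUE`: a truncated outline falsifies every descriptor).
#' @param fill_holes see [cell_shape()].
#' @param smooth_window see [trace_outline()].
#' @return list of [cell_shape()] objects (possibly empty), labels as in the
#'   raster.
#' @export
extract_cells <- function(seg, exclude_border = TRUE, fill_holes = TRUE,
                          smooth_window = 1L) {
  raster <- seg$raster
  nlab <- max(raster)
  if (nlab == 0L) {
    return(list())
  }
  nr <- nrow(raster)
  nc <- ncol(raster)
  border <- unique(c(raster[1L, ], raster[nr, ], raster[, 1L], raster[, nc]))
  pos <- which(raster > 0L)
  labs <- raster[pos]
  prow <- ((pos - 1L) %% nr) + 1L
  pcol <- ((pos - 1L) %/% nr) + 1L
  bylab <- split(seq_along(pos), labs)
  shapes <- vector("list", length(bylab))
  kept <- 0L
  for (nm in names(bylab)) {
    lb <- as.integer(nm)
    if (exclude_border && lb %in% border) next
    i <- bylab[[nm]]
    rr <- range(prow[i])
    cc <- range(pcol[i])
    crop <- matrix(FALSE, rr[2L] - rr[1L] + 1L, cc[2L] - cc[1L] + 1L)
    crop[cbind(prow[i] - rr[1L] + 1L, pcol[i] - cc[1L] + 1L)] <- TRUE
    kept <- kept + 1L
    shapes[[kept]] <- cell_shape(crop, label = lb,
                                 offset = c(rr[1L] - 1L, cc[1L] - 1L),
                                 fill_holes = fill_holes,
                                 smooth_window = smooth_window)
  }
  shapes[seq_len(kept)]
}

#' Measure a set of images into a feature table
#'
#' Runs [extract_cells()] + [shape_features()] over one or more segmented
#' images, optionally restricted to grid-selected cells.
#'
#' @param images a [segmented_image()] or list of them.
#' @param config a [geometry_config()].
#' @param exclude_border see [extract_cells()].
#' @param selected optional named list: for each `image_id`, the integer cell
#'   ids to keep (as from [select_cells()]).
#' @return `data.frame` with `image_id`, `cell_id`, `group_label` and one
#'   column per descriptor.
#' @export
measure_cells <- function(images, config = geometry_config(),
                          exclude_border = TRUE, selected = NULL) {
  if (inherits(images, "segmented_image")) {
    images <- list(images)
  }
  rows <- list()
  for (seg in images) {
    shapes <- extract_cells(seg, exclude_border = exclude_border,
                            fill_holes = config$fill_holes,
                            smooth_window = config$smooth_window)
    if (!is.null(selected)) {
      keep <- selected[[seg$image_id]]
      shapes <- Filter(function(s) s$label %in% keep, shapes)
    }
    shapes <- Filter(function(s) nrow(s$pixels) >= config$min_area_px, shapes)
    for (s in shapes) {
      f <- shape_features(s, config)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(image_id = seg$image_id,
                         cell_id = s$label,
                         group_label = seg$group_label,
                         stringsAsFactors = FALSE),
              f)
    }
  }
  if (length(rows) == 0L) {
    return(empty_feature_table())
  }
  do.call(rbind, rows)
}

empty_feature_table <- function() {
  cols <- c("image_id", "cell_id", "group_label", feature_names())
  df <- as.data.frame(matrix(numeric(0), 0L, length(cols)))
  names(df) <- cols
  df$image_id <- character(0)
  df$group_label <- character(0)
  df$cell_id <- integer(0)
  df
}

#' Write / read a feature table as CSV
#'
#' The CSV round-trip is lossless to better than 1e-9 relative (values are
#' written with 15 significant digits). `read_feature_table()` validates the
#' schema and errors naming any missing column.
#'
#' @param table feature table (`data.frame` as from [measure_cells()]).
#' @param path CSV file path.
#' @return `read_feature_table()` returns the validated `data.frame`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_id", "cell_id", "group_label", feature_names())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("feature table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  df
}
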