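#' Pipeline run configuration
#'
#' Bundles every stage's parameters so a run is reproducible from its echoed
#' configuration alone.
#'
#' @param scene a [scene_config()] for simulation mode, or `NULL` when
#'   loading images from `input_dirs`.
#' @param input_dirs optional named list `list(treated =, untreated =)` of
#'   directories of label-mask images (PNG/TIFF), used instead of simulation.
#' @param grid a [grid_spec()] for systematic cell selection, or `NULL` to
#'   measure every cell.
#' @param geometry a [geometry_config()].
#' @param stats a [stats_config()].
#' @param seed integer seed; in simulation mode it overrides `scene$seed`.
#' @return list of class `run_config`.
#' @export
run_config <- function(scene = scene_config(), input_dirs = NULL,
                       grid = grid_spec(30), geometry = geometry_config(),
                       stats = stats_config(), seed = NULL) {
  if (!is.null(seed) && !is.null(scene)) {
    scene$seed <- as.integer(seed)
  }
  structure(list(scene = scene, input_dirs = input_dirs, grid = grid,
                 geometry = geometry, stats = stats, seed = seed),
            class = "run_config")
}

#' Run the full morphometry pipeline
#'
#' Simulate (or load) segmented images, select cells with the systematic
#' point grid, measure every descriptor on the selected cells, and rank the
#' descriptors by ROC AUC with KS screening and pairwise AUC comparisons.
#'
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, the feature table,
#'   ranking, pairwise matrix, selection report and config echo are written
#'   there as CSV/txt.
#' @return list of class `pipeline_result`: `features`, `report` (a
#'   `rank_report`), `selection` (`data.frame` image_id/cell_id/selected),
#'   `truth` (simulation ground truth or `NULL`), `images`, `config`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  if (!is.null(config$input_dirs)) {
    images <- list()
    for (group in names(config$input_dirs)) {
      paths <- sort(list.files(config$input_dirs[[group]],
                               pattern = "\\.(png|tif|tiff)$",
                               ignore.case = TRUE, full.names = TRUE))
      for (p in paths) {
        seg <- load_segmentation(p, group_label = group)
        images[[seg$image_id]] <- seg
      }
    }
    truth <- NULL
  } else {
    scenes <- make_scene_set(config$scene)
    images <- scenes$images
    truth <- scenes$truth
  }
  if (length(images) == 0L) {
    stop("no cells measured: empty image set")
  }
  selection <- NULL
  selected <- NULL
  if (!is.null(config$grid)) {
    selected <- lapply(images, function(seg) {
      pts <- grid_points(dim(seg$raster), config$grid)
      select_cells(seg, pts)
    })
    selection <- do.call(rbind, lapply(names(images), function(id) {
      n <- max(images[[id]]$raster)
      if (n == 0L) {
        return(NULL)
      }
      data.frame(image_id = id, cell_id = seq_len(n),
                 selected = seq_len(n) %in% selected[[id]],
                 stringsAsFactors = FALSE)
    }))
  }
  features <- measure_cells(images, config = config$geometry,
                            selected = selected)
  if (nrow(features) == 0L) {
    stop("no cells measured")
  }
  report <- rank_parameters(features, config = config$stats)
  result <- structure(list(features = features, report = report,
                           selection = selection, truth = truth,
                           images = images, config = config),
                      class = "pipeline_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(output_dir, "features.csv"))
    utils::write.csv(report$ranking, file.path(output_dir, "ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$pairwise_p),
                     file.path(output_dir, "pairwise_auc_p.csv"))
    if (!is.null(selection)) {
      utils::write.csv(selection, file.path(output_dir, "selection.csv"),
                       row.names = FALSE)
    }
    if (!is.null(truth)) {
      utils::write.csv(truth, file.path(output_dir, "ground_truth.csv"),
                       row.names = FALSE)
    }
    writeLines(c(sprintf("cellmorph %s",
                         as.character(utils::packageVersion("cellmorph"))),
                 sprintf("R %s", getRversion()),
                 sprintf("seed %s",
                         if (is.null(config$scene)) "NA"
                         else config$scene$seed),
                 sprintf("n_cells %d", nrow(features))),
               file.path(output_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cells from %d images\n",
              nrow(x$features), length(x$images)))
  print(x$report)
  invisible(x)
}

#' Montage of cell crops sorted by a descriptor
#'
#' Arranges the binary crops of every measured cell of one image in a grid,
#' ordered by the chosen descriptor ascending (ties broken stably by cell
#' id) — the classical "sort objects" view used to eyeball a shape gradient.
#'
#' @param seg a [segmented_image()].
#' @param features feature table containing this image's cells.
#' @param key descriptor name to sort by.
#' @param pad pixels of spacing between tiles.
#' @return numeric matrix (0 background, 1 cell) with attribute `order`
#'   giving the cell ids left-to-right, top-to-bottom.
#' @export
sort_objects_montage <- function(seg, features, key = "roundness", pad = 2L) {
  if (!key %in% feature_names()) {
    stop("unknown descriptor '", key, "'; valid keys: ",
         paste(feature_names(), collapse = ", "))
  }
  rows <- features[features$image_id == seg$image_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no measured cells for image ", seg$image_id)
  }
  ord <- rows$cell_id[order(rows[[key]], rows$cell_id)]
  shapes <- extract_cells(seg, exclude_border = FALSE)
  names(shapes) <- vapply(shapes, function(s) as.character(s$label),
                          character(1L))
  crops <- lapply(as.character(ord), function(id) shapes[[id]]$mask)
  th <- max(vapply(crops, nrow, integer(1L))) + pad
  tw <- max(vapply(crops, ncol, integer(1L))) + pad
  k <- length(crops)
  ncols <- ceiling(sqrt(k))
  nrows <- ceiling(k / ncols)
  canvas <- matrix(0, nrows * th + pad, ncols * tw + pad)
  for (i in seq_len(k)) {
    r <- (i - 1L) %/% ncols
    c <- (i - 1L) %% ncols
    m <- crops[[i]]
    r0 <- r * th + pad + 1L
    c0 <- c * tw + pad + 1L
    canvas[r0:(r0 + nrow(m) - 1L), c0:(c0 + ncol(m) - 1L)] <-
      pmax(canvas[r0:(r0 + nrow(m) - 1L), c0:(c0 + ncol(m) - 1L)], m * 1)
  }
  attr(canvas, "order") <- ord
  canvas
}
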