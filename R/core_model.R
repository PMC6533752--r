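# Data model for TMA cores and ROIs, image I/O, tile stitching, the
# no-signal exclusion rule, the long-format observation table, and the
# end-to-end pipeline driver.

#' ROI annotation
#'
#' A half-open rectangle `[x0, x1) x [y0, y1)` in 0-based pixel coordinates
#' of either the H&E or the SHG image.
#'
#' @param roi_id identifier, unique within a cohort.
#' @param x0,y0,x1,y1 rectangle bounds; `x1 > x0`, `y1 > y0`.
#' @param space `"he"` or `"shg"`.
#' @return an object of class `roi_annotation`.
#' @export
roi_annotation <- function(roi_id, x0, y0, x1, y1, space = c("he", "shg")) {
  space <- match.arg(space)
  if (x1 <= x0 || y1 <= y0) {
    stopf("ROI '%s' has empty bounds [%s,%s)x[%s,%s)", roi_id, x0, x1, y0, y1)
  }
  structure(list(roi_id = as.character(roi_id),
                 x0 = x0, y0 = y0, x1 = x1, y1 = y1, space = space),
            class = "roi_annotation")
}

#' TMA core record
#'
#' One patient's tissue-microarray core: identifiers, grade label, image
#' references, ROI annotations, and exclusion status.
#'
#' @param core_id,patient_id identifiers (one core per patient).
#' @param grade `"grade1"` or `"grade4"`.
#' @param shg_image path to the stitched SHG TIFF, or a list of
#'   `list(path =, x =, y =)` tile entries to be stitched on load.
#' @param he_image optional path to the H&E TIFF.
#' @param rois list of [roi_annotation()].
#' @param excluded logical; `exclusion_reason` records why.
#' @param truth optional generator ground truth (never read by the
#'   measurement pipeline).
#' @return an object of class `tma_core`.
#' @export
tma_core <- function(core_id, patient_id, grade, shg_image,
                     he_image = NULL, rois = list(), excluded = FALSE,
                     exclusion_reason = NA_character_, truth = NULL) {
  grade <- match.arg(grade, c("grade1", "grade4"))
  structure(list(core_id = as.character(core_id),
                 patient_id = as.character(patient_id),
                 grade = grade, shg_image = shg_image, he_image = he_image,
                 rois = rois, excluded = isTRUE(excluded),
                 exclusion_reason = exclusion_reason, truth = truth),
            class = "tma_core")
}

#' Read a grayscale image from TIFF
#'
#' Multi-channel images are reduced to the first channel.
#'
#' @param path TIFF file path.
#' @return grayscale matrix in `[0, 1]`.
#' @export
read_gray_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read an RGB image from TIFF
#' @param path TIFF file path.
#' @return `(h, w, 3)` array in `[0, 1]`.
#' @export
read_rgb_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 3) stopf("'%s' is not an RGB image", path)
  img[, , 1:3]
}

# Load a core's SHG image, stitching tiles when the reference is a tile list.
load_core_shg <- function(core) {
  ref <- core$shg_image
  if (is.character(ref)) return(read_gray_tiff(ref))
  tiles <- lapply(ref, function(t) read_gray_tiff(t$path))
  offsets <- lapply(ref, function(t) c(t$x, t$y))
  stitch_tiles(tiles, offsets)
}

#' Stitch image tiles into a whole-core image
#'
#' Places each tile at its integer pixel offset; the output canvas is the
#' bounding box of all placed tiles and overlapping pixels are resolved by
#' the mean of the contributing tiles. Uncovered canvas pixels are zero.
#'
#' @param tiles list of grayscale matrices.
#' @param offsets list of integer `c(x, y)` offsets of each tile's top-left
#'   corner (0-based canvas coordinates).
#' @return stitched grayscale matrix.
#' @export
stitch_tiles <- function(tiles, offsets) {
  if (length(tiles) == 0) stopf("empty tile list")
  if (length(tiles) != length(offsets)) {
    stopf("tiles and offsets differ in length")
  }
  storage <- unique(vapply(tiles, function(t) typeof(t), character(1)))
  if (length(storage) > 1) stopf("tiles have mismatched bit depth/storage")
  ox <- vapply(offsets, `[`, numeric(1), 1)
  oy <- vapply(offsets, `[`, numeric(1), 2)
  if (any(ox != round(ox)) || any(oy != round(oy))) {
    stopf("tile offsets must be integer pixel positions")
  }
  ws <- vapply(tiles, ncol, integer(1))
  hs <- vapply(tiles, nrow, integer(1))
  x_min <- min(ox)
  y_min <- min(oy)
  if (x_min < 0 || y_min < 0) stopf("tile offsets must be nonnegative")
  W <- max(ox + ws)
  H <- max(oy + hs)
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_along(tiles)) {
    rows <- (oy[i] + 1):(oy[i] + hs[i])
    cols <- (ox[i] + 1):(ox[i] + ws[i])
    acc[rows, cols] <- acc[rows, cols] + tiles[[i]]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  covered <- cnt > 0
  acc[covered] <- acc[covered] / cnt[covered]
  acc
}

#' Crop an ROI out of an image
#'
#' Exact half-open crop `[x0, x1) x [y0, y1)`. An ROI partially outside the
#' image is clipped to the bounds with a warning; an ROI with zero-area
#' intersection is an error.
#'
#' @param image grayscale matrix.
#' @param roi a [roi_annotation()] in the image's pixel space.
#' @return cropped matrix.
#' @export
crop_roi <- function(image, roi) {
  w <- ncol(image)
  h <- nrow(image)
  x0 <- max(0, roi$x0)
  y0 <- max(0, roi$y0)
  x1 <- min(w, roi$x1)
  y1 <- min(h, roi$y1)
  if (x1 <= x0 || y1 <= y0) {
    stopf("ROI '%s' does not intersect the image", roi$roi_id)
  }
  if (x0 != roi$x0 || y0 != roi$y0 || x1 != roi$x1 || y1 != roi$y1) {
    warnf("ROI '%s' clipped to image bounds", roi$roi_id)
  }
  image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
}

#' Exclude cores without SHG signal
#'
#' A core is excluded when the foreground fraction of its binarized
#' (band-pass preprocessed) SHG image falls below
#' `config$no_signal_foreground_fraction` in every available field (each
#' tile when the core is tiled, otherwise the whole image). Unreadable
#' images flag the core as an error rather than dropping it silently.
#' Retained and excluded cores partition the input.
#'
#' @param cores list of [tma_core()].
#' @param config a [pipeline_config()].
#' @return list with `retained` and `excluded` core lists; excluded cores
#'   carry `exclusion_reason`.
#' @export
exclude_no_signal_cores <- function(cores, config = pipeline_config()) {
  retained <- list()
  excluded <- list()
  for (core in cores) {
    fields <- tryCatch({
      if (is.character(core$shg_image)) {
        list(read_gray_tiff(core$shg_image))
      } else {
        lapply(core$shg_image, function(t) read_gray_tiff(t$path))
      }
    }, error = function(e) e)
    if (inherits(fields, "error")) {
      core$excluded <- TRUE
      core$exclusion_reason <- paste("image read error:",
                                     conditionMessage(fields))
      excluded[[length(excluded) + 1]] <- core
      next
    }
    fracs <- vapply(fields, function(img) {
      mask <- suppressWarnings(
        binarize(preprocess(img, config), config$binarize_method,
                 threshold = config$fixed_threshold)
      )
      mean(mask)
    }, numeric(1))
    if (all(fracs < config$no_signal_foreground_fraction)) {
      core$excluded <- TRUE
      core$exclusion_reason <- sprintf(
        "no SHG signal: foreground fraction %.5f < %.5f in all %d field(s)",
        max(fracs), config$no_signal_foreground_fraction, length(fracs))
      excluded[[length(excluded) + 1]] <- core
    } else {
      retained[[length(retained) + 1]] <- core
    }
  }
  list(retained = retained, excluded = excluded)
}

#' Build the long-format observation table
#'
#' One row per ROI of every retained core, carrying the patient id, grade
#' indicator, and the three per-ROI metrics. Alignment is `NA` wherever the
#' minimum-fiber rule withheld it (and, under
#' `config$alignment_drop = "per_core"`, for every ROI of a core with any
#' failing ROI).
#'
#' @param cores list of retained [tma_core()].
#' @param metrics data frame with columns `core_id, roi_id, density,
#'   alignment, intensity_fraction` covering every ROI of every core.
#' @param config a [pipeline_config()].
#' @return data frame with columns `patient_id, core_id, grade, g, roi_id,
#'   density, alignment, intensity_fraction`.
#' @export
build_observation_table <- function(cores, metrics,
                                    config = pipeline_config()) {
  if (anyDuplicated(metrics$roi_id)) {
    stopf("duplicate roi_id in metrics: %s",
          paste(unique(metrics$roi_id[duplicated(metrics$roi_id)]),
                collapse = ", "))
  }
  rows <- list()
  for (core in cores) {
    for (roi in core$rois) {
      m <- metrics[metrics$roi_id == roi$roi_id, ]
      if (nrow(m) == 0) {
        stopf("no metrics for ROI '%s' of core '%s'", roi$roi_id,
              core$core_id)
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = core$patient_id,
        core_id = core$core_id,
        grade = core$grade,
        g = as.integer(core$grade == "grade4"),
        roi_id = roi$roi_id,
        density = m$density,
        alignment = m$alignment,
        intensity_fraction = m$intensity_fraction
      )
    }
  }
  tab <- do.call(rbind, rows)
  if (config$alignment_drop == "per_core") {
    bad_cores <- unique(tab$core_id[is.na(tab$alignment)])
    tab$alignment[tab$core_id %in% bad_cores] <- NA_real_
  }
  tab
}

#' Read a cohort manifest
#'
#' Parses a `cores.json` manifest (as written by [generate_cohort()]) into a
#' list of [tma_core()] objects. Generator ground truth, when present, is
#' kept under `$truth` and is not used by the pipeline.
#'
#' @param path manifest path; relative image paths resolve against its
#'   directory.
#' @return list of `tma_core`.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path)
  base <- dirname(path)
  lapply(man$cores, function(c) {
    rois <- lapply(c$rois, function(r) {
      roi_annotation(r$roi_id, r$x0, r$y0, r$x1, r$y1, space = r$space)
    })
    resolve <- function(p) {
      if (is.null(p)) NULL else file.path(base, p)
    }
    tma_core(c$core_id, c$patient_id, c$grade,
             shg_image = resolve(c$shg_image),
             he_image = resolve(c$he_image),
             rois = rois, truth = c$truth)
  })
}

#' Run the full measurement pipeline
#'
#' Executes, per core: no-signal exclusion, H&E-to-SHG registration (or the
#' nominal pixel-size scaling when `register = FALSE` or no H&E image is
#' available), ROI transformation and cropping, fiber extraction, and the
#' per-ROI metrics; then fits the grade comparison models. Per-core failures
#' are recorded and the remaining cores continue. Fully deterministic given
#' the config seeds.
#'
#' @param cores list of [tma_core()] (e.g. from [read_manifest()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes
#'   `roi_metrics.csv`, `model_summary.json`, `boxplot_summary.csv`,
#'   `transforms.json`, and `exclusions.log`.
#' @param register estimate the H&E-to-SHG transform by registration; when
#'   `FALSE` ROIs are mapped by the nominal pixel-size ratio alone.
#' @param fit_models fit the grade-comparison mixed models (requires both
#'   grades present with at least two patients each).
#' @return list with `table` (observation rows), `metrics`, `report` (from
#'   [compare_grades()], or `NULL`), `retained`, `excluded`, `transforms`,
#'   `failures`.
#' @export
run_pipeline <- function(cores, config = pipeline_config(), out_dir = NULL,
                         register = TRUE, fit_models = TRUE) {
  split <- exclude_no_signal_cores(cores, config)
  retained <- split$retained
  r <- config$he_pixel_size_um / config$shg_pixel_size_um
  metrics <- list()
  transforms <- list()
  failures <- list()
  for (core in retained) {
    res <- tryCatch({
      shg <- load_core_shg(core)
      tr <- if (register && !is.null(core$he_image)) {
        he <- read_rgb_tiff(core$he_image)
        reg <- register_core(shg, he, config)
        transforms[[core$core_id]] <- list(
          matrix = reg$transform$A, translation = reg$transform$b,
          model = reg$transform$model, metric = reg$metric,
          converged = reg$converged)
        reg$transform
      } else {
        similarity2d(scale = r)
      }
      for (roi in core$rois) {
        roi_shg <- if (roi$space == "he") {
          transform_roi(roi, tr, shg_size_px = c(ncol(shg), nrow(shg)))
        } else {
          roi
        }
        crop <- suppressWarnings(crop_roi(shg, roi_shg))
        m <- roi_metrics(crop, config)
        metrics[[length(metrics) + 1]] <- data.frame(
          core_id = core$core_id, roi_id = roi$roi_id,
          density = m$n_valid_fibers, alignment = m$alignment_R,
          intensity_fraction = m$intensity_fraction)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      failures[[core$core_id]] <- res
    }
  }
  metrics <- do.call(rbind, metrics)
  ok_cores <- Filter(function(c) !c$core_id %in% names(failures), retained)
  tab <- build_observation_table(ok_cores, metrics, config)
  report <- NULL
  if (fit_models) {
    report <- compare_grades(tab, config)
  }
  out <- list(table = tab, metrics = metrics, report = report,
              retained = retained, excluded = split$excluded,
              transforms = transforms, failures = failures)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(out, out_dir)
  }
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$table, file.path(out_dir, "roi_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(out$report)) {
    jsonlite::write_json(out$report$models,
                         file.path(out_dir, "model_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    utils::write.csv(out$report$boxplots,
                     file.path(out_dir, "boxplot_summary.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(out$transforms,
                       file.path(out_dir, "transforms.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  lines <- c(
    vapply(out$excluded, function(c) {
      sprintf("%s\t%s", c$core_id, c$exclusion_reason)
    }, character(1)),
    vapply(names(out$failures), function(id) {
      sprintf("%s\tstage failure: %s", id, out$failures[[id]])
    }, character(1))
  )
  writeLines(lines, file.path(out_dir, "exclusions.log"))
  invisible(out)
}
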