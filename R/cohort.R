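# Synthetic cohort generation: a set of TMA cores across two grade groups
# with known ground truth, written as TIFFs plus CSV/JSON tables so the
# whole pipeline can run exactly as it would on real data.

#' Specification of a synthetic two-group cohort
#'
#' @param n_cores_per_group integer pair: annotated cores in the
#'   grade-1-like and grade-4-like groups (blank cores included).
#' @param rois_per_core ROIs per core: a single integer in `{2, 3}`, or a
#'   list of two integer vectors (one per group, one entry per core).
#' @param group_specs list of two [synthetic_spec()] (grade-1-like,
#'   grade-4-like).
#' @param patient_effect_sd between-core (= between-patient) SD of the
#'   per-core shift applied to `fiber_count_mean`, inducing within-patient
#'   correlation of ROI densities.
#' @param n_blank_cores_per_group integer pair: cores per group rendered as
#'   background only (the last cores of each group); these model the
#'   no-SHG-signal cores and carry a ground-truth `blank` flag.
#' @param roi_size_he_px ROI side length in H&E pixels.
#' @param max_offset_px,max_rot_deg bounds of the uniform random similarity
#'   perturbation (SHG px, degrees) applied to each core's true H&E-to-SHG
#'   transform; the pipeline never sees these values.
#' @param seed global integer seed; per-core streams derive from it by a
#'   fixed scheme so cohorts are reproducible core-by-core.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cores_per_group,
                        rois_per_core = 3L,
                        group_specs,
                        patient_effect_sd = 0,
                        n_blank_cores_per_group = c(0L, 0L),
                        roi_size_he_px = 400L,
                        max_offset_px = 6,
                        max_rot_deg = 3,
                        seed = 1L) {
  n_cores_per_group <- as.integer(n_cores_per_group)
  n_blank_cores_per_group <- as.integer(n_blank_cores_per_group)
  if (length(n_cores_per_group) != 2) stopf("field 'n_cores_per_group' must be a pair")
  check_positive(n_cores_per_group, "n_cores_per_group")
  check_nonnegative(n_blank_cores_per_group, "n_blank_cores_per_group")
  if (any(n_blank_cores_per_group > n_cores_per_group)) {
    stopf("more blank cores than cores in a group")
  }
  if (is.numeric(rois_per_core) && length(rois_per_core) == 1) {
    rois_per_core <- list(rep(as.integer(rois_per_core), n_cores_per_group[1]),
                          rep(as.integer(rois_per_core), n_cores_per_group[2]))
  }
  if (!is.list(rois_per_core) || length(rois_per_core) != 2 ||
      length(rois_per_core[[1]]) != n_cores_per_group[1] ||
      length(rois_per_core[[2]]) != n_cores_per_group[2]) {
    stopf("field 'rois_per_core' must be an integer or a per-core list")
  }
  if (!all(unlist(rois_per_core) %in% 2:3)) {
    stopf("field 'rois_per_core' entries must be 2 or 3")
  }
  if (length(group_specs) != 2) stopf("field 'group_specs' must hold two specs")
  lapply(group_specs, validate_synthetic_spec)
  check_nonnegative(patient_effect_sd, "patient_effect_sd")
  structure(list(
    n_cores_per_group = n_cores_per_group,
    rois_per_core = rois_per_core,
    group_specs = group_specs,
    patient_effect_sd = patient_effect_sd,
    n_blank_cores_per_group = n_blank_cores_per_group,
    roi_size_he_px = as.integer(roi_size_he_px),
    max_offset_px = max_offset_px,
    max_rot_deg = max_rot_deg,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic cohort on disk
#'
#' Renders every core's SHG image (16-bit grayscale TIFF) and pseudo-H&E
#' image (8-bit RGB TIFF), annotates 2-3 ROIs per core in H&E coordinates,
#' and writes `ground_truth_fibers.csv`, `ground_truth_rois.csv` and a
#' `cores.json` manifest. Blank cores render as background/noise only and
#' are flagged in the ground truth. Each core's true H&E-to-SHG transform
#' is a small random similarity perturbation on top of the pixel-size
#' scaling; it is recorded under the manifest's `truth` entry and never
#' consumed by the pipeline. Fully deterministic given `cohort$seed`.
#'
#' @param cohort a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `cores` (list of [tma_core()]),
#'   `manifest` (path to `cores.json`), `fibers` and `rois` (ground-truth
#'   data frames).
#' @export
generate_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grades <- c("grade1", "grade4")
  cores <- list()
  fiber_rows <- list()
  roi_rows <- list()
  manifest_cores <- list()
  idx <- 0L
  for (g in 1:2) {
    n <- cohort$n_cores_per_group[g]
    n_blank <- cohort$n_blank_cores_per_group[g]
    gspec <- cohort$group_specs[[g]]
    shift <- with_seed(derive_seed(cohort$seed, 555000 + g), {
      stats::rnorm(n, 0, cohort$patient_effect_sd)
    })
    for (i in seq_len(n)) {
      idx <- idx + 1L
      core_id <- sprintf("G%d_C%03d", c(1, 4)[g], i)
      patient_id <- sprintf("P%04d", idx)
      blank <- i > n - n_blank
      spec <- gspec
      spec$seed <- derive_seed(cohort$seed, idx)
      spec$blank <- blank
      spec$fiber_count_mean <- max(0, gspec$fiber_count_mean + shift[i])
      truth <- sample_fiber_population(spec)
      shg <- render_shg_image(truth)
      offset <- with_seed(derive_seed(cohort$seed, 777000 + idx), {
        similarity2d(1, stats::runif(1, -cohort$max_rot_deg,
                                     cohort$max_rot_deg),
                     stats::runif(1, -cohort$max_offset_px,
                                  cohort$max_offset_px),
                     stats::runif(1, -cohort$max_offset_px,
                                  cohort$max_offset_px))
      })
      he <- render_pseudo_he_image(truth, offset)
      tmap <- attr(he, "true_transform")

      shg_path <- sprintf("%s_shg.tif", core_id)
      he_path <- sprintf("%s_he.tif", core_id)
      tiff::writeTIFF(pmin(shg / 4, 1), file.path(out_dir, shg_path),
                      bits.per.sample = 16L)
      tiff::writeTIFF(he, file.path(out_dir, he_path),
                      bits.per.sample = 8L)

      rois <- place_rois(cohort, spec, tmap,
                         n_rois = cohort$rois_per_core[[g]][i],
                         core_id = core_id,
                         seed = derive_seed(cohort$seed, 888000 + idx))
      core <- tma_core(core_id, patient_id, grades[g],
                       shg_image = file.path(out_dir, shg_path),
                       he_image = file.path(out_dir, he_path),
                       rois = rois,
                       truth = list(blank = blank, transform = tmap))
      cores[[idx]] <- core

      if (nrow(truth$fibers) > 0) {
        ft <- truth$fibers
        ft$core_id <- core_id
        fiber_rows[[length(fiber_rows) + 1]] <- ft
      }
      min_len <- 30 * spec$shg_pixel_size_um
      for (roi in rois) {
        tb <- roi_truth_metrics(truth, roi, tmap, min_len)
        tb$core_id <- core_id
        tb$roi_id <- roi$roi_id
        tb$blank <- blank
        roi_rows[[length(roi_rows) + 1]] <- tb
      }
      manifest_cores[[idx]] <- list(
        core_id = core_id, patient_id = patient_id, grade = grades[g],
        shg_image = shg_path, he_image = he_path,
        rois = lapply(rois, function(r) {
          list(roi_id = r$roi_id, x0 = r$x0, y0 = r$y0, x1 = r$x1,
               y1 = r$y1, space = r$space)
        }),
        truth = list(blank = blank,
                     transform = list(A = tmap$A, b = tmap$b))
      )
    }
  }
  fibers <- if (length(fiber_rows)) do.call(rbind, fiber_rows) else NULL
  rois_df <- do.call(rbind, roi_rows)
  if (!is.null(fibers)) {
    utils::write.csv(fibers, file.path(out_dir, "ground_truth_fibers.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(rois_df, file.path(out_dir, "ground_truth_rois.csv"),
                   row.names = FALSE)
  manifest <- file.path(out_dir, "cores.json")
  jsonlite::write_json(list(cores = manifest_cores), manifest,
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cores = cores, manifest = manifest, fibers = fibers,
                 rois = rois_df))
}

# Place n axis-aligned ROIs (H&E coordinates) whose images under the true
# transform fall inside the SHG bounds.
place_rois <- function(cohort, spec, tmap, n_rois, core_id, seed) {
  w_shg <- spec$image_size_px[1]
  h_shg <- spec$image_size_px[2]
  r <- spec$he_pixel_size_um / spec$shg_pixel_size_um
  w_he <- ceiling(w_shg / r)
  h_he <- ceiling(h_shg / r)
  s <- cohort$roi_size_he_px
  if (s >= min(w_he, h_he)) {
    stopf("roi_size_he_px (%d) does not fit the H&E image (%dx%d)",
          s, w_he, h_he)
  }
  with_seed(seed, {
    rois <- list()
    for (k in seq_len(n_rois)) {
      for (attempt in 1:200) {
        x0 <- round(stats::runif(1, 0, w_he - s - 1))
        y0 <- round(stats::runif(1, 0, h_he - s - 1))
        corners <- rbind(c(x0, y0), c(x0 + s, y0), c(x0, y0 + s),
                         c(x0 + s, y0 + s))
        m <- affine_apply(tmap, corners)
        if (all(m[, 1] >= 0 & m[, 1] <= w_shg - 1 &
                m[, 2] >= 0 & m[, 2] <= h_shg - 1)) break
      }
      rois[[k]] <- roi_annotation(sprintf("%s_R%d", core_id, k),
                                  x0, y0, x0 + s, y0 + s, space = "he")
    }
    rois
  })
}

# Ground-truth per-ROI metrics: valid-fiber count and alignment of the
# fibers whose midpoints fall inside the ROI mapped to SHG coordinates.
roi_truth_metrics <- function(truth, roi, tmap, min_len_um, n_min = 20L) {
  corners <- rbind(c(roi$x0, roi$y0), c(roi$x1, roi$y0),
                   c(roi$x0, roi$y1), c(roi$x1, roi$y1))
  m <- affine_apply(tmap, corners)
  xr <- range(m[, 1])
  yr <- range(m[, 2])
  f <- truth$fibers
  if (nrow(f) == 0) {
    return(data.frame(n_fibers = 0L, n_valid_fibers = 0L,
                      true_alignment = NA_real_))
  }
  mx <- (f$x0 + f$x1) / 2
  my <- (f$y0 + f$y1) / 2
  inside <- mx >= xr[1] & mx < xr[2] & my >= yr[1] & my < yr[2]
  valid <- inside & f$length_um > min_len_um
  R <- alignment_coefficient(f$orientation_deg[valid], n_min = n_min)
  data.frame(n_fibers = sum(inside), n_valid_fibers = sum(valid),
             true_alignment = R)
}

#' The bookkeeping cohort scenario
#'
#' Encodes the study's cohort structure at reduced image size: 75 annotated
#' grade-1 cores of which the last 5 are blank (no SHG signal) and 55
#' annotated grade-4 cores of which the last 4 are blank; every retained
#' grade-1 core carries 3 ROIs (70 x 3 = 210 observations) and the retained
#' grade-4 cores carry 2-3 ROIs (one core with 2, fifty with 3, for 152
#' observations). Images render at 320 x 320 SHG px to keep the full
#' 130-core cohort tractable; the grade-4-like group has higher fiber
#' density and orientation concentration.
#'
#' @param seed global seed.
#' @param image_size_px SHG render size.
#' @return a [cohort_spec()].
#' @export
paper_cohort_spec <- function(seed = 1L, image_size_px = c(320L, 320L)) {
  g1 <- synthetic_spec(image_size_px = image_size_px,
                       fiber_count_mean = 60, orientation_mean_deg = 90,
                       orientation_kappa = 1.0,
                       length_log_mean_um = log(8), length_log_sd_um = 0.3,
                       fiber_width_um = 0.5)
  g4 <- synthetic_spec(image_size_px = image_size_px,
                       fiber_count_mean = 100, orientation_mean_deg = 90,
                       orientation_kappa = 1.3,
                       length_log_mean_um = log(8), length_log_sd_um = 0.3,
                       fiber_width_um = 0.5)
  cohort_spec(
    n_cores_per_group = c(75L, 55L),
    rois_per_core = list(rep(3L, 75), c(2L, rep(3L, 54))),
    group_specs = list(g1, g4),
    patient_effect_sd = 8,
    n_blank_cores_per_group = c(5L, 4L),
    roi_size_he_px = 40L,
    seed = seed
  )
}

#' The calibrated grade-contrast scenario
#'
#' A reduced-size two-group cohort for end-to-end runs: the grade-4-like
#' group has higher fiber density (a ~1.8-fold contrast, mirroring the
#' relative density difference between grades) and higher orientation
#' concentration (kappa 1.3 vs 1.0, whose population resultant lengths
#' differ by 0.096, mirroring the alignment contrast), with between-patient
#' variation of density switched on. Per-image fiber counts (141 vs 254 at
#' 480 x 480 SHG px with 100 H&E px ROIs) put roughly 50 and 90 true valid
#' fibers in each ROI, comfortably above the 20-fiber alignment minimum so
#' the small-sample bias of the resultant length stays secondary to the
#' group contrast. 18 cores per group, 3 ROIs each.
#'
#' @param seed global seed.
#' @param n_cores_per_group cores per group.
#' @return a [cohort_spec()].
#' @export
paper_like_cohort_spec <- function(seed = 1L, n_cores_per_group = c(18L, 18L)) {
  size <- c(480L, 480L)
  g1 <- synthetic_spec(image_size_px = size, fiber_count_mean = 141,
                       orientation_mean_deg = 90, orientation_kappa = 1.0,
                       length_log_mean_um = log(8), length_log_sd_um = 0.3,
                       fiber_width_um = 0.5)
  g4 <- synthetic_spec(image_size_px = size, fiber_count_mean = 254,
                       orientation_mean_deg = 90, orientation_kappa = 1.3,
                       length_log_mean_um = log(8), length_log_sd_um = 0.3,
                       fiber_width_um = 0.5)
  cohort_spec(
    n_cores_per_group = n_cores_per_group,
    rois_per_core = 3L,
    group_specs = list(g1, g4),
    patient_effect_sd = 12,
    n_blank_cores_per_group = c(0L, 0L),
    roi_size_he_px = 100L,
    seed = seed
  )
}
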