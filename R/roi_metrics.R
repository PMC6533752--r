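# Per-ROI collagen measures: density (valid-fiber count), alignment
# (mean resultant length of axial orientations), and the intensity-based
# density cross-check (foreground pixel fraction).

#' Collagen density of an ROI
#'
#' The number of valid fibers in the ROI. The input is expected to have
#' passed [filter_valid_fibers()]; ROI area is constant across the study so
#' the raw count is proportional to an areal density.
#'
#' @param valid_fibers list of `fiber_trace` objects.
#' @return nonnegative integer count.
#' @export
collagen_density <- function(valid_fibers) {
  length(valid_fibers)
}

#' Alignment coefficient of a set of fiber orientations
#'
#' Mean resultant vector length of the orientations, ranging from 0 (no
#' preferred axis) to 1 (perfect alignment). Fiber orientations are axial
#' (defined modulo 180 degrees), so by default the resultant is computed on
#' doubled angles:
#' `R = (1/n) * sqrt((sum cos 2theta)^2 + (sum sin 2theta)^2)`.
#' With fewer than `n_min` orientations the coefficient is statistically
#' unreliable and `NA` is returned.
#'
#' @param orientations_deg axial angles in degrees, in `[0, 180)`; values
#'   outside are normalized modulo 180 with a warning.
#' @param n_min minimum number of fibers required (default 20).
#' @param doubling compute on doubled angles (default `TRUE`; `FALSE` gives
#'   the plain-angle resultant for sensitivity analysis).
#' @return value in `[0, 1]`, or `NA` when `length(orientations_deg) < n_min`.
#' @export
alignment_coefficient <- function(orientations_deg, n_min = 20L,
                                  doubling = TRUE) {
  if (length(orientations_deg) < n_min) return(NA_real_)
  if (any(orientations_deg < 0 | orientations_deg >= 180)) {
    warnf("orientations outside [0, 180) normalized modulo 180")
    orientations_deg <- orientations_deg %% 180
  }
  mult <- if (doubling) 2 else 1
  a <- mult * orientations_deg * pi / 180
  sqrt(sum(cos(a))^2 + sum(sin(a))^2) / length(a)
}

#' Intensity-based collagen density
#'
#' Fraction of foreground ("white") pixels in the binarized ROI: the
#' intensity-based cross-check of the fiber-count density.
#'
#' @param roi_image grayscale ROI matrix (used only for dimension checking;
#'   may be `NULL`).
#' @param mask logical foreground mask from [binarize()] on the same ROI.
#' @return value in `[0, 1]`.
#' @export
intensity_density <- function(roi_image, mask) {
  if (!is.null(roi_image) && !all(dim(roi_image) == dim(mask))) {
    stopf("mask dimensions do not match the ROI image")
  }
  mean(mask)
}

#' Compute all metrics for one ROI image
#'
#' Runs preprocessing, binarization, fiber extraction and the validity
#' filter on an SHG ROI crop, then computes density, alignment and the
#' intensity fraction.
#'
#' @param roi_image grayscale SHG ROI.
#' @param config a [pipeline_config()].
#' @return list with `n_valid_fibers`, `alignment_R` (`NA` below the fiber
#'   minimum), `intensity_fraction`, and `fibers` (the valid
#'   `fiber_trace` list).
#' @export
roi_metrics <- function(roi_image, config = pipeline_config()) {
  pp <- preprocess(roi_image, config)
  mask <- binarize(pp, config$binarize_method,
                   threshold = config$fixed_threshold)
  fibers <- filter_valid_fibers(
    extract_fibers(pp, config, preprocessed = TRUE), config
  )
  ori <- vapply(fibers, `[[`, numeric(1), "orientation_deg")
  list(
    n_valid_fibers = collagen_density(fibers),
    alignment_R = alignment_coefficient(ori, config$n_min_alignment,
                                        config$axial_doubling),
    intensity_fraction = intensity_density(roi_image, mask),
    fibers = fibers
  )
}

#' Orientation histogram of an ROI
#'
#' 18 bins of 10 degrees over the axial range, for QC output.
#'
#' @param orientations_deg axial angles in `[0, 180)`.
#' @return data frame with `bin_start_deg`, `bin_end_deg`, `count`.
#' @export
orientation_histogram <- function(orientations_deg) {
  breaks <- seq(0, 180, by = 10)
  counts <- tabulate(findInterval(orientations_deg %% 180, breaks,
                                  all.inside = TRUE), 18L)
  data.frame(bin_start_deg = breaks[-19], bin_end_deg = breaks[-1],
             count = counts)
}
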