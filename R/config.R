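#' Pipeline configuration
#'
#' Central container for every tunable of the measurement pipeline. The two
#' length-threshold fields express the same validity rule on different
#' scales and must agree: a fiber is valid when it is longer than
#' `min_fiber_length_px` SHG pixels, i.e. `min_fiber_length_um` micrometers
#' at `shg_pixel_size_um` per pixel (defaults 30 px and 5.301 um at
#' 0.1767 um/px; consistency is enforced within 2%).
#'
#' @param shg_pixel_size_um,he_pixel_size_um pixel sizes in micrometers.
#' @param min_fiber_length_px validity threshold in SHG pixels (strictly
#'   greater-than comparison).
#' @param min_fiber_length_um the same threshold in micrometers; defaults to
#'   `min_fiber_length_px * shg_pixel_size_um`.
#' @param n_min_alignment minimum number of valid fibers for the alignment
#'   coefficient to be reported for an ROI.
#' @param no_signal_foreground_fraction cores whose binarized foreground
#'   fraction falls below this in every available field are excluded as
#'   having no SHG signal.
#' @param binarize_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold for `binarize_method = "fixed"`.
#' @param fiber_width_um expected fiber width; sets the band-pass scale of
#'   the extractor's preprocessing.
#' @param r_min_px minimum distance-transform radius for a nucleation point.
#' @param step_px ridge-tracing step length in pixels.
#' @param max_turn_deg maximum turning angle per tracing step, degrees.
#' @param link_gap_px maximum end-to-end gap bridged when linking collinear
#'   traces.
#' @param link_angle_deg angle tolerance for linking collinear traces.
#' @param orientation_method `"pca"` (principal axis of the centerline) or
#'   `"endpoints"` (end-to-end axial angle).
#' @param axial_doubling compute the alignment coefficient on doubled angles
#'   (the standard treatment for axial data); `FALSE` gives the plain-angle
#'   resultant for sensitivity analysis.
#' @param alignment_drop `"per_roi"` (default: ROIs failing the fiber-count
#'   rule lose only their alignment value) or `"per_core"` (all ROIs of a
#'   core are dropped from the alignment analysis if any ROI fails).
#' @param registration list of registration settings: `model`,
#'   `pyramid_levels`, `downscale`, `smooth_sigma_px`, `kmeans_k`, `seed`.
#' @param seed integer seed for the pipeline's stochastic steps.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(shg_pixel_size_um = 0.1767,
                            he_pixel_size_um = 0.505,
                            min_fiber_length_px = 30L,
                            min_fiber_length_um = min_fiber_length_px * shg_pixel_size_um,
                            n_min_alignment = 20L,
                            no_signal_foreground_fraction = 0.001,
                            binarize_method = c("otsu", "fixed"),
                            fixed_threshold = NULL,
                            fiber_width_um = 1.0,
                            r_min_px = 1.5,
                            step_px = 2,
                            max_turn_deg = 30,
                            link_gap_px = 4,
                            link_angle_deg = 20,
                            orientation_method = c("pca", "endpoints"),
                            axial_doubling = TRUE,
                            alignment_drop = c("per_roi", "per_core"),
                            registration = list(),
                            seed = 1L) {
  reg <- utils::modifyList(
    list(model = "similarity", pyramid_levels = 3L, downscale = 2,
         smooth_sigma_px = 2, kmeans_k = 3L, seed = 1L),
    registration
  )
  cfg <- list(
    shg_pixel_size_um = shg_pixel_size_um,
    he_pixel_size_um = he_pixel_size_um,
    min_fiber_length_px = min_fiber_length_px,
    min_fiber_length_um = min_fiber_length_um,
    n_min_alignment = as.integer(n_min_alignment),
    no_signal_foreground_fraction = no_signal_foreground_fraction,
    binarize_method = match.arg(binarize_method),
    fixed_threshold = fixed_threshold,
    fiber_width_um = fiber_width_um,
    r_min_px = r_min_px,
    step_px = step_px,
    max_turn_deg = max_turn_deg,
    link_gap_px = link_gap_px,
    link_angle_deg = link_angle_deg,
    orientation_method = match.arg(orientation_method),
    axial_doubling = isTRUE(axial_doubling),
    alignment_drop = match.arg(alignment_drop),
    registration = reg,
    seed = as.integer(seed)
  )
  check_positive(cfg$shg_pixel_size_um, "shg_pixel_size_um")
  check_positive(cfg$he_pixel_size_um, "he_pixel_size_um")
  check_nonnegative(cfg$min_fiber_length_px, "min_fiber_length_px")
  check_nonnegative(cfg$min_fiber_length_um, "min_fiber_length_um")
  check_nonnegative(cfg$no_signal_foreground_fraction,
                    "no_signal_foreground_fraction")
  implied <- cfg$min_fiber_length_px * cfg$shg_pixel_size_um
  if (implied > 0 &&
      abs(cfg$min_fiber_length_um - implied) > 0.02 * max(implied, 1e-12)) {
    stopf(paste("min_fiber_length_um (%.4f) inconsistent with",
                "min_fiber_length_px x shg_pixel_size_um (%.4f)"),
          cfg$min_fiber_length_um, implied)
  }
  if (cfg$binarize_method == "fixed" && is.null(cfg$fixed_threshold)) {
    stopf("binarize_method 'fixed' requires 'fixed_threshold'")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys override the [pipeline_config()] defaults; unknown keys
#' are rejected.
#'
#' @param path file path (`.yaml`, `.yml`, or `.json`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
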