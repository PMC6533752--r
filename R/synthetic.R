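#' Specification of a synthetic SHG core image
#'
#' Bundles every parameter of the synthetic fibrous-core generator: imaging
#' geometry (image size, SHG and H&E pixel size), the ground-truth fiber
#' population (expected count, axial von Mises orientation distribution,
#' lognormal length distribution, width), and the imaging model (Gaussian
#' point-spread function, background, Poisson shot noise, Gaussian read
#' noise). Defaults emulate a ~600 um tissue-microarray core imaged at
#' 0.1767 um/px with paired H&E at 0.505 um/px.
#'
#' @param image_size_px integer pair `c(width, height)` of the SHG image.
#' @param shg_pixel_size_um SHG pixel size in micrometers.
#' @param he_pixel_size_um H&E pixel size in micrometers.
#' @param fiber_count_mean expected number of fibers in the image (Poisson).
#' @param orientation_mean_deg mean axial orientation, degrees in `[0, 180)`.
#' @param orientation_kappa von Mises concentration on doubled angles;
#'   `0` gives uniform axial orientations.
#' @param length_log_mean_um,length_log_sd_um meanlog and sdlog of the
#'   lognormal fiber length distribution, in log-micrometers.
#' @param fiber_width_um full width at half maximum of the Gaussian fiber
#'   cross-section, micrometers.
#' @param psf_sigma_um standard deviation of the Gaussian PSF, micrometers
#'   (`0` disables PSF blurring).
#' @param background_level constant background intensity (arbitrary units;
#'   fiber peak amplitude is 1).
#' @param poisson_scale photons per intensity unit for shot noise
#'   (`0` disables Poisson noise).
#' @param gaussian_read_sd standard deviation of additive read noise.
#' @param seed integer seed; all generator randomness derives from it.
#' @param blank if `TRUE` the core carries no fibers and renders as
#'   background plus noise only (used for the no-signal exclusion pathway).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size_px = c(3400, 3400),
                           shg_pixel_size_um = 0.1767,
                           he_pixel_size_um = 0.505,
                           fiber_count_mean = 750,
                           orientation_mean_deg = 90,
                           orientation_kappa = 1,
                           length_log_mean_um = log(15),
                           length_log_sd_um = 0.35,
                           fiber_width_um = 1.0,
                           psf_sigma_um = 0.35,
                           background_level = 0.03,
                           poisson_scale = 40,
                           gaussian_read_sd = 0.01,
                           seed = 1L,
                           blank = FALSE) {
  spec <- list(
    image_size_px = as.integer(image_size_px),
    shg_pixel_size_um = shg_pixel_size_um,
    he_pixel_size_um = he_pixel_size_um,
    fiber_count_mean = fiber_count_mean,
    orientation_mean_deg = orientation_mean_deg,
    orientation_kappa = orientation_kappa,
    length_log_mean_um = length_log_mean_um,
    length_log_sd_um = length_log_sd_um,
    fiber_width_um = fiber_width_um,
    psf_sigma_um = psf_sigma_um,
    background_level = background_level,
    poisson_scale = poisson_scale,
    gaussian_read_sd = gaussian_read_sd,
    seed = as.integer(seed),
    blank = isTRUE(blank)
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  if (length(spec$image_size_px) != 2) stopf("field 'image_size_px' must be a pair")
  check_positive(spec$image_size_px, "image_size_px")
  check_positive(spec$shg_pixel_size_um, "shg_pixel_size_um")
  check_positive(spec$he_pixel_size_um, "he_pixel_size_um")
  check_nonnegative(spec$fiber_count_mean, "fiber_count_mean")
  if (!is.numeric(spec$orientation_mean_deg) ||
      spec$orientation_mean_deg < 0 || spec$orientation_mean_deg >= 180) {
    stopf("field 'orientation_mean_deg' must lie in [0, 180)")
  }
  check_nonnegative(spec$orientation_kappa, "orientation_kappa")
  check_positive(spec$fiber_width_um, "fiber_width_um")
  check_nonnegative(spec$psf_sigma_um, "psf_sigma_um")
  check_nonnegative(spec$background_level, "background_level")
  check_nonnegative(spec$poisson_scale, "poisson_scale")
  check_nonnegative(spec$gaussian_read_sd, "gaussian_read_sd")
  spec
}

#' Sample a ground-truth fiber population
#'
#' Draws the fiber count (Poisson around `fiber_count_mean`), axial
#' orientations from the doubled-angle von Mises distribution, lognormal
#' lengths, and uniform midpoints; fibers are straight segments clipped to
#' the image bounds. Deterministic for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed seed for this draw; defaults to `spec$seed`.
#' @param min_separation_px when positive, fibers are placed sequentially by
#'   rejection sampling so that no two centerlines approach within this many
#'   pixels (used to build non-overlapping test populations); placements that
#'   cannot be satisfied after 100 attempts are dropped, so the realized
#'   count may fall below the Poisson draw.
#' @return an object of class `fiber_truth` with elements `spec`, `blank`,
#'   `fibers` (one row per fiber: endpoints in SHG px, `orientation_deg` in
#'   `[0, 180)`, `length_px`, `length_um`) and `centerlines` (list of n x 2
#'   point matrices at ~1 px spacing).
#' @export
sample_fiber_population <- function(spec, seed = spec$seed,
                                    min_separation_px = 0) {
  validate_synthetic_spec(spec)
  w <- spec$image_size_px[1]
  h <- spec$image_size_px[2]
  px <- spec$shg_pixel_size_um
  with_seed(seed, {
    n <- if (spec$blank) 0L else stats::rpois(1, spec$fiber_count_mean)
    claimed <- if (min_separation_px > 0) matrix(FALSE, h, w) else NULL
    sep <- ceiling(min_separation_px)
    centerlines <- list()
    rows <- list()
    for (i in seq_len(n)) {
      for (attempt in seq_len(if (min_separation_px > 0) 100L else 1L)) {
        theta <- sample_axial_orientations(1, spec$orientation_mean_deg,
                                           spec$orientation_kappa)
        len_px <- stats::rlnorm(1, spec$length_log_mean_um,
                                spec$length_log_sd_um) / px
        mx <- stats::runif(1, 0, w - 1)
        my <- stats::runif(1, 0, h - 1)
        ux <- cos(theta * pi / 180)
        uy <- sin(theta * pi / 180)
        seg <- clip_segment(mx - len_px / 2 * ux, my - len_px / 2 * uy,
                            mx + len_px / 2 * ux, my + len_px / 2 * uy,
                            0, w - 1, 0, h - 1)
        # guard against floating-point overshoot of the clip bounds
        seg <- pmin(pmax(seg, 0), c(w - 1, h - 1, w - 1, h - 1))
        lp <- sqrt((seg[3] - seg[1])^2 + (seg[4] - seg[2])^2)
        k <- max(2L, ceiling(lp) + 1L)
        tt <- seq(0, 1, length.out = k)
        cl <- cbind(x = seg[1] + tt * (seg[3] - seg[1]),
                    y = seg[2] + tt * (seg[4] - seg[2]))
        if (!is.null(claimed)) {
          idx <- cbind(round(cl[, 2]) + 1, round(cl[, 1]) + 1)
          if (any(claimed[idx])) next
          for (j in seq_len(nrow(cl))) {
            xr <- max(0, round(cl[j, 1]) - sep):min(w - 1, round(cl[j, 1]) + sep)
            yr <- max(0, round(cl[j, 2]) - sep):min(h - 1, round(cl[j, 2]) + sep)
            claimed[yr + 1, xr + 1] <- TRUE
          }
        }
        centerlines[[length(centerlines) + 1]] <- cl
        rows[[length(rows) + 1]] <- data.frame(
          fiber_id = length(rows) + 1L,
          x0 = seg[1], y0 = seg[2], x1 = seg[3], y1 = seg[4],
          orientation_deg = theta, length_px = lp, length_um = lp * px
        )
        break
      }
    }
    fibers <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(fiber_id = integer(0), x0 = numeric(0), y0 = numeric(0),
                 x1 = numeric(0), y1 = numeric(0),
                 orientation_deg = numeric(0), length_px = numeric(0),
                 length_um = numeric(0))
    structure(list(spec = spec, blank = spec$blank, fibers = fibers,
                   centerlines = centerlines),
              class = "fiber_truth")
  })
}

# Noise-free fiber intensity layer: each fiber is a segment with a Gaussian
# cross-section of FWHM fiber_width_um; overlapping fibers add.
render_fiber_layer <- function(truth) {
  spec <- truth$spec
  w <- spec$image_size_px[1]
  h <- spec$image_size_px[2]
  img <- matrix(0, h, w)
  if (nrow(truth$fibers) == 0) return(img)
  sigma <- spec$fiber_width_um / (2 * sqrt(2 * log(2))) / spec$shg_pixel_size_um
  pad <- ceiling(3 * sigma + 1)
  for (i in seq_len(nrow(truth$fibers))) {
    f <- truth$fibers[i, ]
    cx0 <- max(0L, floor(min(f$x0, f$x1)) - pad)
    cx1 <- min(w - 1L, ceiling(max(f$x0, f$x1)) + pad)
    cy0 <- max(0L, floor(min(f$y0, f$y1)) - pad)
    cy1 <- min(h - 1L, ceiling(max(f$y0, f$y1)) + pad)
    xs <- cx0:cx1
    ys <- cy0:cy1
    gx <- rep(xs, each = length(ys))
    gy <- rep(ys, times = length(xs))
    dx <- f$x1 - f$x0
    dy <- f$y1 - f$y0
    L2 <- dx * dx + dy * dy
    tt <- if (L2 == 0) rep(0, length(gx)) else
      pmin(1, pmax(0, ((gx - f$x0) * dx + (gy - f$y0) * dy) / L2))
    d2 <- (gx - (f$x0 + tt * dx))^2 + (gy - (f$y0 + tt * dy))^2
    img[cbind(gy + 1, gx + 1)] <- img[cbind(gy + 1, gx + 1)] +
      exp(-d2 / (2 * sigma^2))
  }
  img
}

#' Render a synthetic SHG image
#'
#' Draws every ground-truth fiber as a polyline with Gaussian cross-section,
#' convolves with the Gaussian PSF, adds the background floor, and (when
#' `noise = TRUE`) applies Poisson shot noise followed by Gaussian read
#' noise. Noise is drawn from a stream derived from the spec seed, so the
#' render is bit-reproducible.
#'
#' @param truth a [sample_fiber_population()] result.
#' @param noise logical; apply the noise model.
#' @return grayscale image matrix (rows = y); attribute `pixel_size_um`.
#' @export
render_shg_image <- function(truth, noise = TRUE) {
  spec <- truth$spec
  img <- render_fiber_layer(truth)
  sigma_psf <- spec$psf_sigma_um / spec$shg_pixel_size_um
  if (sigma_psf > 0.2) {
    img <- as.matrix(EBImage::gblur(img, sigma = sigma_psf))
  }
  img <- img + spec$background_level
  if (noise && (spec$poisson_scale > 0 || spec$gaussian_read_sd > 0)) {
    img <- with_seed(derive_seed(spec$seed, 999983), {
      out <- img
      if (spec$poisson_scale > 0) {
        out <- matrix(stats::rpois(length(out), out * spec$poisson_scale),
                      nrow(out), ncol(out)) / spec$poisson_scale
      }
      if (spec$gaussian_read_sd > 0) {
        out <- out + matrix(stats::rnorm(length(out), 0, spec$gaussian_read_sd),
                            nrow(out), ncol(out))
      }
      out
    })
    img[img < 0] <- 0
  }
  attr(img, "pixel_size_um") <- spec$shg_pixel_size_um
  img
}

#' Render the paired pseudo-H&E bright-field image
#'
#' Produces an RGB rendering of the same core at the H&E pixel scale: white
#' background, eosin-pink tissue over a disk core footprint, pink deepened
#' along collagen-dense regions, and a sparse speckle of hematoxylin-purple
#' nuclei. The image is generated by inverse warping through the true
#' H&E-to-SHG map `offset o scale(he_px/shg_px)`; `offset` (a perturbation in
#' SHG pixel coordinates) is recorded in the returned attribute
#' `true_transform` as ground truth for registration tests, and is never
#' consumed by the measurement pipeline. Blank cores render all white.
#'
#' @param truth a [sample_fiber_population()] result.
#' @param offset an [affine2d()] perturbation (identity by default).
#' @param nuclei_per_100um2 expected nuclei count per 100 square micrometers
#'   of tissue footprint.
#' @return RGB array `(h, w, 3)` in `[0, 1]`; attributes `true_transform`
#'   (full H&E px -> SHG px `affine2d`) and `pixel_size_um`.
#' @export
render_pseudo_he_image <- function(truth, offset = NULL,
                                   nuclei_per_100um2 = 0.6) {
  spec <- truth$spec
  if (is.null(offset)) offset <- affine2d(model = "similarity")
  r <- spec$he_pixel_size_um / spec$shg_pixel_size_um
  tfull <- affine_compose(offset, similarity2d(scale = r))
  w_shg <- spec$image_size_px[1]
  h_shg <- spec$image_size_px[2]
  w_he <- ceiling(w_shg / r)
  h_he <- ceiling(h_shg / r)
  out <- array(1, dim = c(h_he, w_he, 3))
  if (truth$blank || nrow(truth$fibers) == 0) {
    attr(out, "true_transform") <- tfull
    attr(out, "pixel_size_um") <- spec$he_pixel_size_um
    return(out)
  }

  fib <- render_fiber_layer(truth)
  cx <- (w_shg - 1) / 2
  cy <- (h_shg - 1) / 2
  radius <- 0.47 * min(w_shg, h_shg)

  # nuclei speckle rasterized in SHG space
  nuc <- matrix(0, h_shg, w_shg)
  nuc_r <- 1.5 / spec$shg_pixel_size_um
  area_um2 <- pi * (radius * spec$shg_pixel_size_um)^2
  n_nuc <- round(nuclei_per_100um2 * area_um2 / 100)
  nuc_xy <- with_seed(derive_seed(spec$seed, 424243), {
    rho <- radius * sqrt(stats::runif(n_nuc))
    ang <- stats::runif(n_nuc, 0, 2 * pi)
    cbind(cx + rho * cos(ang), cy + rho * sin(ang))
  })
  rr <- ceiling(nuc_r)
  for (i in seq_len(n_nuc)) {
    xs <- max(0, round(nuc_xy[i, 1]) - rr):min(w_shg - 1, round(nuc_xy[i, 1]) + rr)
    ys <- max(0, round(nuc_xy[i, 2]) - rr):min(h_shg - 1, round(nuc_xy[i, 2]) + rr)
    gx <- rep(xs, each = length(ys))
    gy <- rep(ys, times = length(xs))
    hit <- (gx - nuc_xy[i, 1])^2 + (gy - nuc_xy[i, 2])^2 <= nuc_r^2
    nuc[cbind(gy[hit] + 1, gx[hit] + 1)] <- 1
  }

  g <- pixel_grid(h_he, w_he)
  p <- affine_apply(tfull, cbind(g$x, g$y))
  in_disk <- (p[, 1] - cx)^2 + (p[, 2] - cy)^2 <= radius^2
  fval <- bilinear_sample(fib, p[, 1], p[, 2])
  nval <- bilinear_sample(nuc, p[, 1], p[, 2])
  tissue <- in_disk | fval > 0.25

  pink <- c(0.94, 0.75, 0.84)
  deep <- c(0.84, 0.45, 0.64)
  purple <- c(0.42, 0.28, 0.58)
  wgt <- pmin(1, fval / 0.8)
  for (ch in 1:3) {
    plane <- rep(1, h_he * w_he)
    plane[tissue] <- (1 - wgt[tissue]) * pink[ch] + wgt[tissue] * deep[ch]
    nidx <- tissue & nval > 0.5
    plane[nidx] <- purple[ch]
    out[, , ch] <- matrix(plane, h_he, w_he)
  }
  attr(out, "true_transform") <- tfull
  attr(out, "pixel_size_um") <- spec$he_pixel_size_um
  out
}
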