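# H&E -> SHG registration: color k-means segmentation of the H&E image, a
# tissue-density grayscale proxy, multi-resolution intensity registration,
# and a landmark least-squares fallback.

#' Color segmentation of an H&E image by k-means
#'
#' Clusters pixels in RGB space with a seed-fixed k-means++-style
#' initialization (ties broken by lowest cluster index). The background
#' cluster is the one whose mean color lies closest to white; the tissue
#' mask is the union of all other clusters.
#'
#' @param he RGB array `(h, w, 3)` in `[0, 1]`.
#' @param k number of clusters (default 3: background / eosin /
#'   hematoxylin).
#' @param seed integer seed for the initialization.
#' @return list with `labels` (integer matrix), `tissue_mask` (logical
#'   matrix), and `centers` (k x 3 mean colors).
#' @export
segment_he_kmeans <- function(he, k = 3L, seed = 1L) {
  if (k < 2) stopf("k must be at least 2")
  h <- dim(he)[1]
  w <- dim(he)[2]
  px <- cbind(as.vector(he[, , 1]), as.vector(he[, , 2]), as.vector(he[, , 3]))
  uniq <- unique(round(px, 6))
  if (nrow(uniq) < k) {
    warnf("image has fewer than k distinct colors: single-cluster result")
    labels <- matrix(1L, h, w)
    centers <- matrix(colMeans(px), 1, 3)
    tissue <- matrix(sum((centers[1, ] - 1)^2) > 0.01, h, w)
    return(list(labels = labels, tissue_mask = tissue, centers = centers))
  }
  centers0 <- with_seed(seed, kmeanspp_init(px, k))
  km <- suppressWarnings(stats::kmeans(px, centers = centers0,
                                       iter.max = 50L))
  labels <- matrix(km$cluster, h, w)
  d_white <- rowSums(sweep(km$centers, 2, c(1, 1, 1))^2)
  bg <- which.min(d_white)
  list(labels = labels, tissue_mask = labels != bg, centers = km$centers)
}

# k-means++ initialization: first center uniform, later centers drawn with
# probability proportional to squared distance from the nearest chosen
# center; ties and draws resolved deterministically under the caller's seed.
kmeanspp_init <- function(px, k) {
  n <- nrow(px)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(px, 2, px[idx[1], ])^2)
  for (i in 2:k) {
    if (sum(d2) <= 0) {
      idx[i] <- sample.int(n, 1)
    } else {
      idx[i] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(px, 2, px[idx[i], ])^2))
  }
  px[idx, , drop = FALSE]
}

#' Tissue-density grayscale proxy of an H&E image
#'
#' H&E and SHG intensities are not directly comparable, so intensity
#' registration runs on a proxy: eosin depth (`1 - green`) inside the
#' k-means tissue mask, with the flat tissue pedestal (the median eosin
#' depth over the mask) subtracted and the result lightly smoothed.
#' Collagen-dense regions render as deeper pink (lower green), so after
#' pedestal removal the proxy is bright where the SHG image is bright and
#' near zero over structureless tissue, which is what makes the
#' mean-squared-difference metric sensitive to the transform.
#'
#' @param he RGB array.
#' @param k,seed passed to [segment_he_kmeans()].
#' @param smooth_sigma_px Gaussian smoothing of the proxy.
#' @return grayscale matrix in `[0, 1]`.
#' @export
he_tissue_proxy <- function(he, k = 3L, seed = 1L, smooth_sigma_px = 1) {
  seg <- segment_he_kmeans(he, k = k, seed = seed)
  depth <- 1 - he[, , 2]
  if (!any(seg$tissue_mask)) {
    return(matrix(0, nrow(depth), ncol(depth)))
  }
  mask <- seg$tissue_mask
  if (k >= 3 && nrow(seg$centers) >= 3) {
    # restrict to the eosin cluster(s): collagen is eosin-stained, while the
    # hematoxylin (nuclei) cluster has no SHG counterpart and would bias the
    # intensity metric. Hematoxylin = darkest cluster (lowest luminance).
    lum <- rowMeans(seg$centers)
    d_white <- rowSums(sweep(seg$centers, 2, c(1, 1, 1))^2)
    bg <- which.min(d_white)
    nonbg <- setdiff(seq_len(nrow(seg$centers)), bg)
    if (length(nonbg) > 1) {
      hema <- nonbg[which.min(lum[nonbg])]
      mask <- mask & !(seg$labels == hema)
    }
  }
  pedestal <- stats::median(depth[mask])
  proxy <- pmax(0, depth - pedestal) * mask
  if (smooth_sigma_px > 0.2) {
    proxy <- as.matrix(EBImage::gblur(proxy, sigma = smooth_sigma_px))
  }
  proxy
}

# Block-mean downsampling by an integer factor (pads the border by edge
# replication when dimensions do not divide evenly).
downsample2 <- function(img, factor = 2L) {
  h <- nrow(img)
  w <- ncol(img)
  h2 <- ceiling(h / factor)
  w2 <- ceiling(w / factor)
  ri <- pmin(rep(1:(h2 * factor), length.out = h2 * factor), h)
  ci <- pmin(rep(1:(w2 * factor), length.out = w2 * factor), w)
  big <- img[ri, ci]
  rg <- (seq_len(h2 * factor) - 1) %/% factor + 1
  cg <- (seq_len(w2 * factor) - 1) %/% factor + 1
  t(rowsum(t(rowsum(big, rg)), cg)) / factor^2
}

#' Resample an image by an isotropic scale factor
#'
#' Bilinear resampling onto a grid whose pixel size is `1/factor` of the
#' input's (so `factor > 1` upsamples).
#'
#' @param img grayscale matrix.
#' @param factor output pixels per input pixel.
#' @return resampled matrix of size `round(dim * factor)`.
#' @export
resample_scale <- function(img, factor) {
  h2 <- max(2L, round(nrow(img) * factor))
  w2 <- max(2L, round(ncol(img) * factor))
  g <- pixel_grid(h2, w2)
  matrix(bilinear_sample(img, g$x / factor, g$y / factor), h2, w2)
}

# Parameter vector <-> affine transform, per model family.
params_to_affine <- function(p, model) {
  switch(model,
    translation = affine2d(diag(2), p, model = "translation"),
    rigid = similarity2d(1, p[1], p[2], p[3], model = "rigid"),
    similarity = similarity2d(exp(p[1]), p[2], p[3], p[4],
                              model = "similarity"),
    affine = affine2d(matrix(p[1:4], 2, 2), p[5:6], model = "affine")
  )
}

affine_to_params <- function(t, model) {
  pp <- affine_params(t)
  switch(model,
    translation = t$b,
    rigid = c(pp$rot_deg, t$b),
    similarity = c(log(pp$scale), pp$rot_deg, t$b),
    affine = c(as.vector(t$A), t$b)
  )
}

# Mean squared difference between `fixed` and `moving` warped by the forward
# transform t (moving -> fixed coordinates), computed over the overlap;
# returns Inf when the overlap drops below a quarter of the fixed image.
# For large images the metric is evaluated on a regular pixel stride chosen
# to keep ~<= 30k samples (deterministic, so the objective is smooth in t).
warp_mse <- function(fixed, moving, t, max_samples = 30000L) {
  ti <- affine_invert(t)
  h <- nrow(fixed)
  w <- ncol(fixed)
  stride <- max(1L, ceiling(sqrt(h * w / max_samples)))
  xs <- seq(0L, w - 1L, by = stride)
  ys <- seq(0L, h - 1L, by = stride)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  p <- affine_apply(ti, cbind(gx, gy))
  inb <- p[, 1] >= 0 & p[, 1] <= ncol(moving) - 1 &
    p[, 2] >= 0 & p[, 2] <= nrow(moving) - 1
  if (mean(inb) < 0.25) return(Inf)
  mv <- bilinear_sample(moving, p[, 1], p[, 2])
  fv <- fixed[cbind(gy + 1, gx + 1)]
  a <- fv[inb]
  b <- mv[inb]
  # standardize over the overlap: the minimized quantity is the mean squared
  # difference of the z-scored intensities (equivalently 2*(1 - correlation)),
  # which is insensitive to how much of either image the overlap covers
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (sa < 1e-9 || sb < 1e-9) return(Inf)
  mean(((a - mean(a)) / sa - (b - mean(b)) / sb)^2)
}

#' Iterative intensity-based registration
#'
#' Estimates the transform (of the requested family) mapping `moving` into
#' `fixed` coordinates by minimizing the mean squared intensity difference
#' between the Gaussian-smoothed images, with Nelder-Mead over a
#' multi-resolution pyramid (coarse-to-fine). Both images must already share
#' a pixel size. Non-convergence is reported in the `converged` flag, never
#' as an error, so callers can fall back to landmarks.
#'
#' @param fixed grayscale target image (e.g. the SHG core).
#' @param moving grayscale source image (e.g. the resampled tissue proxy).
#' @param model transform family: `"translation"`, `"rigid"`,
#'   `"similarity"`, or `"affine"`.
#' @param init initial `affine2d` (identity by default).
#' @param pyramid_levels number of pyramid levels.
#' @param downscale per-level downsampling factor.
#' @param smooth_sigma_px Gaussian pre-smoothing at full resolution.
#' @param maxit Nelder-Mead iterations per level.
#' @return list with `transform` (`affine2d`, moving -> fixed px), `metric`
#'   (final MSE), `converged` (logical), and `trace` (per-level metric).
#' @export
register_intensity <- function(fixed, moving,
                               model = c("similarity", "translation",
                                         "rigid", "affine"),
                               init = NULL,
                               pyramid_levels = 3L,
                               downscale = 2,
                               smooth_sigma_px = 2,
                               maxit = 300L) {
  model <- match.arg(model)
  if (is.null(init)) init <- affine2d(model = model)
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) < 1e-12) return(x * 0)
    (x - r[1]) / diff(r)
  }
  f0 <- norm01(if (smooth_sigma_px > 0.2)
    as.matrix(EBImage::gblur(fixed, sigma = smooth_sigma_px)) else fixed)
  m0 <- norm01(if (smooth_sigma_px > 0.2)
    as.matrix(EBImage::gblur(moving, sigma = smooth_sigma_px)) else moving)

  pyr_f <- list(f0)
  pyr_m <- list(m0)
  for (l in seq_len(pyramid_levels - 1)) {
    pyr_f[[l + 1]] <- downsample2(pyr_f[[l]], downscale)
    pyr_m[[l + 1]] <- downsample2(pyr_m[[l]], downscale)
  }

  p <- affine_to_params(init, model)
  trace <- numeric(0)
  converged <- TRUE
  for (level in rev(seq_len(pyramid_levels))) {
    sc <- downscale^(level - 1)
    fl <- pyr_f[[level]]
    ml <- pyr_m[[level]]
    # translations live in pixel units of the current level
    p_level <- p
    tix <- switch(model, translation = 1:2, rigid = 2:3,
                  similarity = 3:4, affine = 5:6)
    p_level[tix] <- p[tix] / sc
    obj <- function(q) {
      t <- try(params_to_affine(q, model), silent = TRUE)
      if (inherits(t, "try-error")) return(Inf)
      warp_mse(fl, ml, t)
    }
    scale_par <- rep(1, length(p_level))
    rot_ix <- switch(model, rigid = 1, similarity = 2, integer(0))
    if (length(rot_ix)) scale_par[rot_ix] <- 2
    if (model == "similarity") scale_par[1] <- 0.05
    if (model == "affine") scale_par[1:4] <- 0.05
    fit <- stats::optim(p_level, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, parscale = scale_par,
                                       reltol = 1e-10))
    if (level == 1 && fit$convergence != 0) {
      # restart the simplex once from the current optimum
      fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit,
                                         parscale = scale_par,
                                         reltol = 1e-10))
    }
    p <- fit$par
    p[tix] <- p[tix] * sc
    trace <- c(trace, fit$value)
    if (level == 1) converged <- fit$convergence == 0 && is.finite(fit$value)
  }
  t_final <- params_to_affine(p, model)
  list(transform = t_final, metric = trace[length(trace)],
       converged = converged, trace = trace)
}

#' Least-squares landmark registration
#'
#' Fits the transform of the requested family minimizing the sum of squared
#' distances `sum ||T(p_he) - p_shg||^2`. Translation needs >= 1 pair,
#' rigid/similarity >= 2, affine >= 3 non-collinear pairs.
#'
#' @param he_points n x 2 matrix of source (H&E) points.
#' @param shg_points n x 2 matrix of matching target (SHG) points.
#' @param model transform family.
#' @return an `affine2d` with attribute `rms` (residual root mean square).
#' @export
register_landmarks <- function(he_points, shg_points,
                               model = c("similarity", "translation",
                                         "rigid", "affine")) {
  model <- match.arg(model)
  he_points <- as.matrix(he_points)
  shg_points <- as.matrix(shg_points)
  n <- nrow(he_points)
  if (nrow(shg_points) != n) stopf("landmark point sets differ in size")
  need <- c(translation = 1, rigid = 2, similarity = 2, affine = 3)[model]
  if (n < need) {
    stopf("model '%s' needs at least %d landmark pairs, got %d",
          model, need, n)
  }
  if (model == "translation") {
    t <- affine2d(diag(2), colMeans(shg_points) - colMeans(he_points),
                  model = "translation")
  } else if (model %in% c("rigid", "similarity")) {
    # Umeyama closed-form similarity/rigid fit
    mu_a <- colMeans(he_points)
    mu_b <- colMeans(shg_points)
    A <- sweep(he_points, 2, mu_a)
    B <- sweep(shg_points, 2, mu_b)
    S <- crossprod(B, A) / n
    sv <- svd(S)
    D <- diag(2)
    if (det(sv$u %*% t(sv$v)) < 0) D[2, 2] <- -1
    R <- sv$u %*% D %*% t(sv$v)
    s <- if (model == "similarity") {
      sum(diag(D) * sv$d) / mean(rowSums(A^2))
    } else 1
    t <- affine2d(s * R, mu_b - as.numeric(s * R %*% mu_a), model = model)
  } else {
    cen <- sweep(he_points, 2, colMeans(he_points))
    if (qr(cen)$rank < 2) {
      stopf("affine landmark fit requires non-collinear points")
    }
    X <- cbind(he_points, 1)
    beta <- solve(crossprod(X), crossprod(X, shg_points))
    t <- affine2d(t(beta[1:2, ]), beta[3, ], model = "affine")
  }
  res <- affine_apply(t, he_points) - shg_points
  attr(t, "rms") <- sqrt(mean(rowSums(res^2)))
  t
}

#' Map an ROI annotation into SHG coordinates
#'
#' Transforms the four corners of the half-open rectangle, then snaps to the
#' axis-aligned bounding rectangle rounded outward to integers. The
#' recorded `shift_px` attribute is the distance between the mapped
#' rectangle center and the snapped rectangle center.
#'
#' @param roi a [roi_annotation()] in H&E space.
#' @param t an `affine2d` mapping H&E px -> SHG px.
#' @param shg_size_px optional `c(width, height)`; when supplied, an ROI
#'   mapped fully outside these bounds is an error.
#' @return a [roi_annotation()] in SHG space with attribute `shift_px`.
#' @export
transform_roi <- function(roi, t, shg_size_px = NULL) {
  corners <- rbind(c(roi$x0, roi$y0), c(roi$x1, roi$y0),
                   c(roi$x0, roi$y1), c(roi$x1, roi$y1))
  mapped <- affine_apply(t, corners)
  # snap outward, ignoring floating-point dust from exact rotations
  x0 <- floor(round(min(mapped[, 1]), 9))
  x1 <- ceiling(round(max(mapped[, 1]), 9))
  y0 <- floor(round(min(mapped[, 2]), 9))
  y1 <- ceiling(round(max(mapped[, 2]), 9))
  if (!is.null(shg_size_px)) {
    if (x1 <= 0 || y1 <= 0 || x0 >= shg_size_px[1] || y0 >= shg_size_px[2]) {
      stopf("ROI '%s' maps fully outside the SHG image", roi$roi_id)
    }
  }
  out <- roi_annotation(roi$roi_id, x0, y0, x1, y1, space = "shg")
  mc <- colMeans(mapped[c(1, 4), ])
  sc <- c((x0 + x1) / 2, (y0 + y1) / 2)
  attr(out, "shift_px") <- sqrt(sum((mc - sc)^2))
  out
}

#' Register one core's H&E image to its SHG image
#'
#' The combined registration used by the pipeline: segment the H&E image,
#' build the tissue proxy, resample it to the SHG pixel size using the
#' nominal pixel-size ratio, then estimate the residual transform by
#' intensity registration. The returned transform maps H&E pixel
#' coordinates directly to SHG pixel coordinates.
#'
#' @param shg grayscale SHG image.
#' @param he RGB H&E image.
#' @param config a [pipeline_config()]; `config$registration` supplies
#'   model, pyramid and k-means settings.
#' @return list with `transform` (H&E px -> SHG px), `residual` (the
#'   estimated transform on top of the pixel-size scaling), `metric`,
#'   `converged`.
#' @export
register_core <- function(shg, he, config = pipeline_config()) {
  reg <- config$registration
  r <- config$he_pixel_size_um / config$shg_pixel_size_um
  proxy <- he_tissue_proxy(he, k = reg$kmeans_k, seed = reg$seed,
                           smooth_sigma_px = 1)
  moving <- resample_scale(proxy, r)
  fit <- register_intensity(shg, moving, model = reg$model,
                            pyramid_levels = reg$pyramid_levels,
                            downscale = reg$downscale,
                            smooth_sigma_px = reg$smooth_sigma_px)
  full <- affine_compose(fit$transform, similarity2d(scale = r))
  list(transform = full, residual = fit$transform, metric = fit$metric,
       converged = fit$converged)
}
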