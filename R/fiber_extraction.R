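# Fiber extraction: a FIRE-style tracer over the Euclidean distance
# transform of the binarized SHG image. The stages are (1) band-pass
# preprocessing at the fiber-width scale, (2) binarization, (3) distance
# transform, (4) nucleation at local maxima of the distance map, (5) ridge
# tracing under a step-length/turning-angle constraint, (6) merge/link
# bookkeeping, yielding per-fiber centerlines, arc lengths, axial
# orientations and widths.

#' Preprocess an SHG image for fiber extraction
#'
#' Difference-of-Gaussians band-pass tuned to the configured fiber width:
#' the narrow scale preserves fiber ridges while the wide scale estimates
#' and removes background, so the output is signed with background
#' fluctuating around zero. A constant image maps to (numerically) zero.
#'
#' @param image grayscale matrix.
#' @param config a [pipeline_config()].
#' @return signed grayscale matrix of the same size.
#' @export
preprocess <- function(image, config = pipeline_config()) {
  if (length(image) == 0) stopf("empty image")
  sigma_w <- config$fiber_width_um / (2 * sqrt(2 * log(2))) /
    config$shg_pixel_size_um
  s1 <- max(0.5, sigma_w)
  s2 <- max(3 * s1, s1 + 1)
  lo <- as.matrix(EBImage::gblur(image, sigma = s1))
  hi <- as.matrix(EBImage::gblur(image, sigma = s2))
  lo - hi
}

#' Binarize a grayscale image
#'
#' Foreground is the set of pixels strictly above the threshold. For
#' `method = "otsu"` the threshold is Otsu's histogram threshold on the ROI,
#' subject to an asymmetry guard: after band-pass preprocessing, fiber
#' signal is strictly positive while noise is roughly symmetric about the
#' median, so Otsu's split is accepted only when the upper class lies at
#' least 3 times farther above the median than the lower class lies below
#' it. A pure-noise image fails the guard (ratio near 1, where Otsu would
#' otherwise split the noise distribution near its middle) and yields an
#' empty mask. A constant image gives an empty mask with a warning.
#'
#' @param image grayscale matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold value, required for `method = "fixed"`.
#' @return logical matrix of the same size.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold)) stopf("method 'fixed' requires a threshold value")
    return(image > threshold)
  }
  rng <- range(image)
  if (diff(rng) < 1e-12) {
    warnf("constant image: Otsu binarization returns empty foreground")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  thr <- otsu_threshold(image)
  med <- stats::median(image)
  above <- mean(image[image > thr]) - med
  below <- med - mean(image[image <= thr])
  if (!is.finite(above) || !is.finite(below) || below <= 0 ||
      above / below < 3) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  image > thr
}

# Otsu's threshold on a 256-bin histogram over the image range.
otsu_threshold <- function(image, nbins = 256L) {
  rng <- range(image)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- as.numeric(
    tabulate(findInterval(image, breaks, all.inside = TRUE), nbins)
  )
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[nbins]
  total_m <- m[nbins]
  between <- (total_m * w - total_w * m)^2 /
    (w * (total_w - w) * total_w^2)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Local maxima of a matrix over the 8-neighborhood (plateaus count when the
# pixel equals the neighborhood maximum).
local_maxima <- function(d, min_value) {
  h <- nrow(d)
  w <- ncol(d)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- d
  nbr_max <- matrix(-Inf, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nbr_max <- pmax(nbr_max, pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)])
  }
  which(d >= nbr_max & d > min_value, arr.ind = TRUE)
}

# Integer offsets forming a ring of radius ~step around the origin.
ring_offsets <- function(step) {
  r <- ceiling(step + 1)
  ox <- rep(-r:r, each = 2 * r + 1)
  oy <- rep(-r:r, times = 2 * r + 1)
  d <- sqrt(ox^2 + oy^2)
  keep <- d >= step - 0.6 & d <= step + 0.6
  cbind(ox[keep], oy[keep])
}

# Trace a ridge from (x, y) in direction `dir` (unit 2-vector) along local
# maxima of the distance map d, stepping `step` px with turning angle at
# most `max_turn` degrees. Returns the visited points excluding the start.
trace_direction <- function(d, x, y, dir, step, max_turn, ring) {
  h <- nrow(d)
  w <- ncol(d)
  cos_tol <- cos(max_turn * pi / 180)
  pts <- matrix(numeric(0), ncol = 2)
  for (iter in 1:10000) {
    cx <- ring[, 1] + round(x)
    cy <- ring[, 2] + round(y)
    ok <- cx >= 0 & cx <= w - 1 & cy >= 0 & cy <= h - 1
    if (!any(ok)) break
    cx <- cx[ok]
    cy <- cy[ok]
    vx <- cx - x
    vy <- cy - y
    vn <- sqrt(vx^2 + vy^2)
    ca <- (vx * dir[1] + vy * dir[2]) / vn
    dv <- d[cbind(cy + 1, cx + 1)]
    cand <- ca >= cos_tol & dv > 0.5
    if (!any(cand)) break
    best <- which(cand)[which.max(dv[cand])]
    nx <- cx[best]
    ny <- cy[best]
    dir <- c(nx - x, ny - y) / sqrt((nx - x)^2 + (ny - y)^2)
    x <- nx
    y <- ny
    pts <- rbind(pts, c(x, y))
  }
  pts
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

# Axial orientation in [0, 180) of a point set: principal axis of the
# centered coordinates, or the end-to-end vector.
centerline_orientation <- function(pts, method = "pca") {
  if (method == "endpoints" || nrow(pts) == 2) {
    v <- pts[nrow(pts), ] - pts[1, ]
  } else {
    cc <- sweep(pts, 2, colMeans(pts))
    v <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
  }
  (atan2(v[2], v[1]) * 180 / pi) %% 180
}

#' Extract fiber traces from an SHG image
#'
#' Runs the distance-transform ridge tracer: binarize the (preprocessed)
#' image, take the Euclidean distance transform of the foreground, nucleate
#' at local maxima above `r_min_px`, trace each ridge in both directions
#' with step `step_px` and maximum turning angle `max_turn_deg`, merge
#' traces that mostly revisit already-claimed ridge pixels, and link
#' collinear trace ends separated by at most `link_gap_px`. The result is
#' deterministic for a given image and configuration.
#'
#' @param image grayscale matrix; pass the raw image with
#'   `preprocessed = FALSE` (default) to apply [preprocess()] first.
#' @param config a [pipeline_config()].
#' @param preprocessed set `TRUE` when `image` has already been band-passed.
#' @return list of `fiber_trace` objects, each with `centerline` (n x 2
#'   matrix of 0-based (x, y) points), `length_um`, `length_px`,
#'   `orientation_deg`, `mean_width_px`, and `n_points`.
#' @export
extract_fibers <- function(image, config = pipeline_config(),
                           preprocessed = FALSE) {
  if (!preprocessed) image <- preprocess(image, config)
  mask <- binarize(image, config$binarize_method,
                   threshold = config$fixed_threshold)
  if (!any(mask)) return(list())
  d <- as.matrix(EBImage::distmap(mask * 1))
  seeds <- local_maxima(d, config$r_min_px)
  if (nrow(seeds) == 0) return(list())
  ord <- order(d[seeds], decreasing = TRUE)
  seeds <- seeds[ord, , drop = FALSE]
  ring <- ring_offsets(config$step_px)
  h <- nrow(d)
  w <- ncol(d)
  claimed <- matrix(FALSE, h, w)
  traces <- list()

  claim_radius <- function(pts) {
    for (i in seq_len(nrow(pts))) {
      r <- max(1, d[pts[i, 2] + 1, pts[i, 1] + 1])
      xr <- max(0, round(pts[i, 1] - r)):min(w - 1, round(pts[i, 1] + r))
      yr <- max(0, round(pts[i, 2] - r)):min(h - 1, round(pts[i, 2] + r))
      claimed[yr + 1, xr + 1] <<- TRUE
    }
  }

  for (s in seq_len(nrow(seeds))) {
    y0 <- seeds[s, 1] - 1  # arr.ind: row = y index
    x0 <- seeds[s, 2] - 1
    if (claimed[y0 + 1, x0 + 1]) next
    # initial direction: strongest ring neighbor
    cx <- ring[, 1] + x0
    cy <- ring[, 2] + y0
    ok <- cx >= 0 & cx <= w - 1 & cy >= 0 & cy <= h - 1
    if (!any(ok)) next
    dv <- d[cbind(cy[ok] + 1, cx[ok] + 1)]
    if (max(dv) <= 0.5) next
    best <- which(ok)[which.max(dv)]
    dir0 <- c(ring[best, 1], ring[best, 2])
    dir0 <- dir0 / sqrt(sum(dir0^2))
    fwd <- trace_direction(d, x0, y0, dir0, config$step_px,
                           config$max_turn_deg, ring)
    bwd <- trace_direction(d, x0, y0, -dir0, config$step_px,
                           config$max_turn_deg, ring)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 c(x0, y0), fwd)
    if (nrow(pts) < 2) next
    # merge rule: drop traces that mostly run over already-claimed ridge
    frac_claimed <- mean(claimed[cbind(pts[, 2] + 1, pts[, 1] + 1)])
    if (frac_claimed >= 0.5) next
    claim_radius(pts)
    traces[[length(traces) + 1]] <- pts
  }

  traces <- link_collinear_traces(traces, config)

  lapply(traces, function(pts) {
    width <- 2 * mean(d[cbind(round(pts[, 2]) + 1, round(pts[, 1]) + 1)])
    lp <- polyline_length(pts)
    structure(list(
      centerline = pts,
      length_px = lp,
      length_um = lp * config$shg_pixel_size_um,
      orientation_deg = centerline_orientation(pts, config$orientation_method),
      mean_width_px = width,
      n_points = nrow(pts)
    ), class = "fiber_trace")
  })
}

# Join pairs of traces whose nearest endpoints lie within link_gap_px and
# whose axial orientations agree within link_angle_deg, with the connecting
# segment also collinear with both.
link_collinear_traces <- function(traces, config) {
  if (length(traces) < 2) return(traces)
  axial_diff <- function(a, b) {
    dd <- abs(a - b) %% 180
    min(dd, 180 - dd)
  }
  repeat {
    n <- length(traces)
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- traces[[i]]
        b <- traces[[j]]
        ends_a <- rbind(a[1, ], a[nrow(a), ])
        ends_b <- rbind(b[1, ], b[nrow(b), ])
        dmat <- outer(1:2, 1:2, Vectorize(function(p, q) {
          sqrt(sum((ends_a[p, ] - ends_b[q, ])^2))
        }))
        if (min(dmat) > config$link_gap_px) next
        oa <- centerline_orientation(a)
        ob <- centerline_orientation(b)
        if (axial_diff(oa, ob) > config$link_angle_deg) next
        hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        ea <- hit[1]
        eb <- hit[2]
        gapv <- ends_b[eb, ] - ends_a[ea, ]
        if (sqrt(sum(gapv^2)) > 1e-9) {
          og <- (atan2(gapv[2], gapv[1]) * 180 / pi) %% 180
          if (axial_diff(og, oa) > config$link_angle_deg) next
        }
        if (ea == 1) a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
        if (eb == 2) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
        traces[[i]] <- rbind(a, b)
        traces[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  traces
}

#' Keep only valid fibers
#'
#' Applies the validity rule: a fiber counts when its length is strictly
#' greater than `min_fiber_length_um` (default 5.301 um, i.e. 30 SHG px at
#' 0.1767 um/px). Input order is preserved.
#'
#' @param fibers list of `fiber_trace` objects.
#' @param config a [pipeline_config()]; `min_fiber_length_um` holds the
#'   threshold.
#' @return the filtered list.
#' @export
filter_valid_fibers <- function(fibers, config = pipeline_config()) {
  Filter(function(f) f$length_um > config$min_fiber_length_um, fibers)
}

#' Tabulate fiber traces
#'
#' @param fibers list of `fiber_trace` objects.
#' @param core_id,roi_id identifiers copied into each row.
#' @return data frame with one row per fiber: `core_id, roi_id, fiber_id,
#'   length_um, orientation_deg, mean_width_px, n_points`.
#' @export
fiber_table <- function(fibers, core_id = NA_character_,
                        roi_id = NA_character_) {
  if (length(fibers) == 0) {
    return(data.frame(core_id = character(0), roi_id = character(0),
                      fiber_id = integer(0), length_um = numeric(0),
                      orientation_deg = numeric(0), mean_width_px = numeric(0),
                      n_points = integer(0)))
  }
  data.frame(
    core_id = core_id,
    roi_id = roi_id,
    fiber_id = seq_along(fibers),
    length_um = vapply(fibers, `[[`, numeric(1), "length_um"),
    orientation_deg = vapply(fibers, `[[`, numeric(1), "orientation_deg"),
    mean_width_px = vapply(fibers, `[[`, numeric(1), "mean_width_px"),
    n_points = vapply(fibers, `[[`, numeric(1), "n_points")
  )
}
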