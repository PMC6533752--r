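# Shared fixtures: planted-fiber images and ground-truth matching.

# A fiber_truth with manually planted straight fibers (bypasses sampling).
planted_truth <- function(fibers_df, image_size = c(128, 128),
                          noise = FALSE, ...) {
  spec <- synthetic_spec(image_size_px = image_size, fiber_count_mean = 0,
                         poisson_scale = if (noise) 40 else 0,
                         gaussian_read_sd = if (noise) 0.01 else 0,
                         background_level = if (noise) 0.03 else 0, ...)
  centerlines <- lapply(seq_len(nrow(fibers_df)), function(i) {
    f <- fibers_df[i, ]
    k <- max(2L, ceiling(f$length_px) + 1L)
    tt <- seq(0, 1, length.out = k)
    cbind(x = f$x0 + tt * (f$x1 - f$x0), y = f$y0 + tt * (f$y1 - f$y0))
  })
  structure(list(spec = spec, blank = FALSE, fibers = fibers_df,
                 centerlines = centerlines), class = "fiber_truth")
}

planted_fiber <- function(cx, cy, angle_deg, length_px, id = 1L,
                          px = 0.1767) {
  ux <- cos(angle_deg * pi / 180)
  uy <- sin(angle_deg * pi / 180)
  data.frame(fiber_id = id,
             x0 = cx - length_px / 2 * ux, y0 = cy - length_px / 2 * uy,
             x1 = cx + length_px / 2 * ux, y1 = cy + length_px / 2 * uy,
             orientation_deg = angle_deg %% 180,
             length_px = length_px, length_um = length_px * px)
}

# Greedy matching of extracted fibers to ground-truth segments by mean
# centerline-to-segment distance; returns recall/precision and per-match
# relative length errors.
match_extracted_fibers <- function(truth, fibers, tol_px = 4) {
  n_true <- length(truth$centerlines)
  if (length(fibers) == 0) {
    return(list(recall = 0, precision = NA_real_, length_rel_err = numeric(0)))
  }
  used <- rep(FALSE, n_true)
  tp <- 0L
  errs <- numeric(0)
  for (f in fibers) {
    dmin <- Inf
    best <- NA_integer_
    for (k in seq_len(n_true)) {
      if (used[k]) next
      cl <- truth$centerlines[[k]]
      a <- cl[1, ]
      b <- cl[nrow(cl), ]
      dx <- b[1] - a[1]
      dy <- b[2] - a[2]
      L2 <- dx^2 + dy^2
      tt <- pmin(1, pmax(0,
        ((f$centerline[, 1] - a[1]) * dx + (f$centerline[, 2] - a[2]) * dy) / L2))
      d <- mean(sqrt((f$centerline[, 1] - (a[1] + tt * dx))^2 +
                       (f$centerline[, 2] - (a[2] + tt * dy))^2))
      if (d < dmin) {
        dmin <- d
        best <- k
      }
    }
    if (!is.na(best) && dmin <= tol_px) {
      used[best] <- TRUE
      tp <- tp + 1L
      errs <- c(errs, abs(f$length_px - truth$fibers$length_px[best]) /
                  truth$fibers$length_px[best])
    }
  }
  list(recall = tp / n_true, precision = tp / length(fibers),
       length_rel_err = errs)
}

# Drop ground-truth fibers below the validity threshold.
truth_valid_only <- function(truth, config) {
  keep <- truth$fibers$length_um > config$min_fiber_length_um
  truth$fibers <- truth$fibers[keep, , drop = FALSE]
  truth$centerlines <- truth$centerlines[keep]
  truth
}

# Small cohort written to a session temp dir, cached across tests.
small_cohort_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      size <- c(256L, 256L)
      g1 <- synthetic_spec(image_size_px = size, fiber_count_mean = 50,
                           orientation_kappa = 1,
                           length_log_mean_um = log(8),
                           length_log_sd_um = 0.3, fiber_width_um = 0.5)
      g4 <- synthetic_spec(image_size_px = size, fiber_count_mean = 90,
                           orientation_kappa = 2,
                           length_log_mean_um = log(8),
                           length_log_sd_um = 0.3, fiber_width_um = 0.5)
      ch <- cohort_spec(c(3L, 3L), 2L, list(g1, g4),
                        patient_effect_sd = 6,
                        n_blank_cores_per_group = c(1L, 0L),
                        roi_size_he_px = 36L, seed = 7L)
      dir <- file.path(tempdir(), "fibergrade-small-cohort")
      generate_cohort(ch, dir)
      cache <<- dir
    }
    cache
  }
})
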