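# Band-pass preprocessing, binarization, ridge tracing, validity filter.

test_that("preprocessing preserves ridge structure and flattens constants", {
  cfg <- pipeline_config()
  expect_error(preprocess(matrix(numeric(0), 0, 0), cfg), "empty")

  const <- matrix(0.4, 64, 64)
  expect_lt(max(abs(preprocess(const, cfg))), 1e-8)

  # noise-free rendered fiber: the ridge peak stays on the fiber row
  tr <- planted_truth(planted_fiber(64, 40.0, 0, 90), image_size = c(128, 80))
  img <- render_shg_image(tr, noise = FALSE)
  pp <- preprocess(img, cfg)
  peak_rows <- apply(pp[, 30:100], 2, which.max)
  expect_true(all(abs(peak_rows - 41) <= 0.5))
})

test_that("binarization separates signal from noise", {
  cfg <- pipeline_config()
  # two-level image: any fixed threshold strictly inside recovers the set
  img <- matrix(0, 20, 20)
  img[3:7, 4:12] <- 255
  for (thr in c(1, 127, 254)) {
    expect_equal(binarize(img, "fixed", thr), img == 255)
  }
  # threshold 0 on a strictly positive image: all-foreground
  expect_true(all(binarize(matrix(runif(100) + 0.1, 10, 10), "fixed", 0)))
  expect_error(binarize(img, "fixed"), "threshold")

  # constant image under otsu: empty with a warning
  expect_warning(m <- binarize(matrix(1, 8, 8), "otsu"), "constant")
  expect_false(any(m))

  # pure-noise renders binarize to (near-)empty foreground
  fracs <- vapply(1:5, function(s) {
    spec <- synthetic_spec(image_size_px = c(128, 128), blank = TRUE,
                           seed = s)
    img <- render_shg_image(sample_fiber_population(spec))
    mean(binarize(preprocess(img, cfg), "otsu"))
  }, numeric(1))
  expect_true(all(fracs < 0.01))
})

test_that("single and parallel planted fibers are recovered accurately", {
  cfg <- pipeline_config()
  # one straight 80 px fiber, no noise
  tr <- planted_truth(planted_fiber(64, 64, 25, 80), image_size = c(128, 128))
  img <- render_shg_image(tr, noise = FALSE)
  fb <- extract_fibers(img, cfg)
  expect_length(fb, 1)
  expect_equal(fb[[1]]$length_px, 80, tolerance = 0.10)
  expect_lt(abs(fb[[1]]$orientation_deg - 25), 2)
  expect_equal(fb[[1]]$length_um, fb[[1]]$length_px * cfg$shg_pixel_size_um)
  # arc length consistency with the centerline
  cl <- fb[[1]]$centerline
  arc <- sum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2))
  expect_equal(fb[[1]]$length_px, arc, tolerance = 1e-6)

  # two parallel well-separated fibers
  two <- rbind(planted_fiber(64, 40, 25, 80, id = 1),
               planted_fiber(64, 90, 25, 80, id = 2))
  fb2 <- extract_fibers(render_shg_image(planted_truth(two,
    image_size = c(128, 128)), noise = FALSE), cfg)
  expect_length(fb2, 2)
  for (f in fb2) expect_lt(abs(f$orientation_deg - 25), 2)

  # empty foreground yields an empty list, not an error
  expect_warning(
    empty <- extract_fibers(matrix(0, 32, 32), cfg, preprocessed = TRUE),
    "constant")
  expect_length(empty, 0)
})

test_that("extraction is equivariant to rotation and translation", {
  cfg <- pipeline_config()
  fibs <- rbind(planted_fiber(50, 40, 20, 60, id = 1),
                planted_fiber(90, 100, 115, 70, id = 2))
  img <- render_shg_image(planted_truth(fibs, image_size = c(144, 144)),
                          noise = FALSE)
  fb <- extract_fibers(img, cfg)
  ori <- sort(vapply(fb, `[[`, numeric(1), "orientation_deg"))

  # rotate image by 90 degrees: orientations shift by 90 mod 180
  img90 <- t(img)[, nrow(img):1]
  fb90 <- extract_fibers(img90, cfg)
  ori90 <- sort(vapply(fb90, `[[`, numeric(1), "orientation_deg"))
  expect_length(fb90, length(fb))
  d <- abs(sort((ori + 90) %% 180) - ori90) %% 180
  expect_true(all(pmin(d, 180 - d) < 2))

  # integer translation: same fibers, centerlines shifted, lengths equal
  big <- matrix(0, 176, 176)
  big[17:160, 25:168] <- img  # shift by (x, y) = (24, 16)
  fbt <- extract_fibers(big, cfg)
  expect_length(fbt, length(fb))
  len0 <- sort(vapply(fb, `[[`, numeric(1), "length_px"))
  lent <- sort(vapply(fbt, `[[`, numeric(1), "length_px"))
  expect_equal(lent, len0, tolerance = 0.05)
  c0 <- colMeans(do.call(rbind, lapply(fb, `[[`, "centerline")))
  ct <- colMeans(do.call(rbind, lapply(fbt, `[[`, "centerline")))
  expect_equal(unname(ct - c0), c(24, 16), tolerance = 1)
})

test_that("the validity filter equals a brute-force length filter", {
  cfg <- pipeline_config()
  mk <- function(len_um) structure(list(length_um = len_um),
                                   class = "fiber_trace")
  # printed threshold: 5.3 um keeps exactly the fibers longer than it
  fl <- lapply(c(4.0, 6.0, 10.0), mk)
  expect_length(filter_valid_fibers(fl, cfg), 2)
  expect_length(filter_valid_fibers(lapply(c(1, 3, 5.3), mk), cfg), 0)

  # oracle equivalence on random inputs, including the boundary case
  set.seed(42)
  for (i in 1:20) {
    lens <- c(runif(30, 0, 12), cfg$min_fiber_length_um)
    fl <- lapply(lens, mk)
    got <- vapply(filter_valid_fibers(fl, cfg), `[[`, numeric(1), "length_um")
    expect_identical(got, lens[lens > cfg$min_fiber_length_um])
  }

  # threshold overridden to zero is the identity on positive lengths
  cfg0 <- pipeline_config(min_fiber_length_px = 0L, min_fiber_length_um = 0)
  fl <- lapply(c(0.5, 2, 9), mk)
  expect_length(filter_valid_fibers(fl, cfg0), 3)

  # inconsistent px/um thresholds are rejected
  expect_error(pipeline_config(min_fiber_length_um = 6.5), "inconsistent")
})

test_that("fiber recovery holds on non-overlapping synthetic populations", {
  cfg <- pipeline_config()
  stats <- lapply(1:4, function(s) {
    spec <- synthetic_spec(image_size_px = c(400, 400), fiber_count_mean = 40,
                           length_log_mean_um = log(10),
                           length_log_sd_um = 0.3, orientation_kappa = 1,
                           seed = s)
    tr <- truth_valid_only(sample_fiber_population(spec,
                                                   min_separation_px = 8), cfg)
    fb <- filter_valid_fibers(extract_fibers(render_shg_image(tr), cfg), cfg)
    match_extracted_fibers(tr, fb)
  })
  recall <- mean(vapply(stats, `[[`, numeric(1), "recall"))
  precision <- mean(vapply(stats, `[[`, numeric(1), "precision"))
  med_err <- stats::median(unlist(lapply(stats, `[[`, "length_rel_err")))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  expect_lte(med_err, 0.15)
})
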