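# Stitching, cropping, exclusion, observation table.

test_that("tile stitching places, bounds, and averages correctly", {
  tile <- matrix(runif(64), 8, 8)
  # single tile at the origin is the identity
  expect_equal(stitch_tiles(list(tile), list(c(0, 0))), tile)

  # 2x2 grid without overlap: each quadrant equals its tile
  t2 <- matrix(runif(64), 8, 8)
  t3 <- matrix(runif(64), 8, 8)
  t4 <- matrix(runif(64), 8, 8)
  out <- stitch_tiles(list(tile, t2, t3, t4),
                      list(c(0, 0), c(8, 0), c(0, 8), c(8, 8)))
  expect_equal(dim(out), c(16, 16))
  expect_equal(out[1:8, 1:8], tile)
  expect_equal(out[1:8, 9:16], t2)
  expect_equal(out[9:16, 1:8], t3)
  expect_equal(out[9:16, 9:16], t4)

  # 10 px overlap with values 100 and 200: overlap resolves to the mean 150
  a <- matrix(100, 20, 30)
  b <- matrix(200, 20, 30)
  ov <- stitch_tiles(list(a, b), list(c(0, 0), c(20, 0)))
  expect_equal(dim(ov), c(20, 50))
  expect_true(all(ov[, 1:20] == 100))
  expect_true(all(ov[, 21:30] == 150))
  expect_true(all(ov[, 31:50] == 200))

  expect_error(stitch_tiles(list(), list()), "empty")
  expect_error(stitch_tiles(list(a, matrix(1L, 2, 2)),
                            list(c(0, 0), c(0, 0))), "bit depth")
})

test_that("ROI cropping is exact, clips with a warning, and errors when empty", {
  img <- matrix(seq_len(1024 * 1024), 1024, 1024)
  # full-image ROI is the identity
  expect_equal(crop_roi(img, roi_annotation("full", 0, 0, 1024, 1024,
                                            space = "shg")), img)
  # the standard 400 x 400 ROI convention
  c400 <- crop_roi(img, roi_annotation("r", 0, 0, 400, 400, space = "shg"))
  expect_equal(dim(c400), c(400, 400))
  expect_equal(c400, img[1:400, 1:400])

  # overhanging ROI: clipped by the overhang with a warning
  expect_warning(
    cc <- crop_roi(img, roi_annotation("r2", 674, 0, 1074, 400,
                                       space = "shg")),
    "clipped")
  expect_equal(dim(cc), c(400, 350))

  expect_error(crop_roi(img, roi_annotation("r3", 2000, 0, 2400, 400,
                                            space = "shg")), "intersect")
})

test_that("round-trip crop/paste respects half-open 0-based coordinates", {
  img <- matrix(rnorm(90 * 70), 90, 70)
  roi <- roi_annotation("rt", 13, 27, 44, 61, space = "shg")
  crop <- crop_roi(img, roi)
  expect_equal(dim(crop), c(61 - 27, 44 - 13))
  pasted <- img
  pasted[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1] <- crop
  expect_identical(pasted, img)
})

test_that("no-signal exclusion partitions the cohort as in the study design", {
  cfg <- pipeline_config()
  dir <- small_cohort_dir()
  cores <- read_manifest(file.path(dir, "cores.json"))
  split <- exclude_no_signal_cores(cores, cfg)

  # partition invariant
  expect_equal(length(split$retained) + length(split$excluded), length(cores))
  # exactly the blank core is excluded, with a reason
  expect_length(split$excluded, 1)
  expect_match(split$excluded[[1]]$exclusion_reason, "no SHG signal")
  blank_ids <- vapply(Filter(function(c) isTRUE(c$truth$blank), cores),
                      `[[`, character(1), "core_id")
  expect_equal(split$excluded[[1]]$core_id, blank_ids)

  # threshold 0 excludes nothing
  cfg0 <- pipeline_config(no_signal_foreground_fraction = 0)
  expect_length(exclude_no_signal_cores(cores, cfg0)$excluded, 0)

  # unreadable image flags the core instead of dropping it
  broken <- cores[1]
  broken[[1]]$shg_image <- file.path(dir, "missing.tif")
  sb <- exclude_no_signal_cores(broken, cfg)
  expect_length(sb$excluded, 1)
  expect_match(sb$excluded[[1]]$exclusion_reason, "read error")
})

test_that("observation table bookkeeping follows the ROI structure", {
  cores <- list(
    tma_core("c1", "p1", "grade1", "a.tif", rois = list(
      roi_annotation("c1_r1", 0, 0, 10, 10),
      roi_annotation("c1_r2", 0, 0, 10, 10))),
    tma_core("c2", "p2", "grade4", "b.tif", rois = list(
      roi_annotation("c2_r1", 0, 0, 10, 10)))
  )
  metrics <- data.frame(
    core_id = c("c1", "c1", "c2"),
    roi_id = c("c1_r1", "c1_r2", "c2_r1"),
    density = c(25, 5, 40),
    alignment = c(0.5, NA, 0.7),
    intensity_fraction = c(0.2, 0.05, 0.3))
  tab <- build_observation_table(cores, metrics)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$patient_id[1:2], c("p1", "p1"))
  expect_equal(tab$g, c(0, 0, 1))
  # a 5-fiber ROI keeps its density but has no alignment
  expect_equal(tab$density[2], 5)
  expect_true(is.na(tab$alignment[2]))

  dup <- rbind(metrics, metrics[1, ])
  expect_error(build_observation_table(cores, dup), "duplicate")

  # per-core dropping blanks every ROI of an affected core
  cfg_core <- pipeline_config(alignment_drop = "per_core")
  tab2 <- build_observation_table(cores, metrics, cfg_core)
  expect_true(all(is.na(tab2$alignment[tab2$core_id == "c1"])))
  expect_false(is.na(tab2$alignment[tab2$core_id == "c2"]))
})

test_that("cohort generation is reproducible and seed-disjoint", {
  dir1 <- file.path(tempdir(), "coh-a")
  dir2 <- file.path(tempdir(), "coh-b")
  dir3 <- file.path(tempdir(), "coh-c")
  size <- c(128L, 128L)
  g <- synthetic_spec(image_size_px = size, fiber_count_mean = 25,
                      length_log_mean_um = log(6), fiber_width_um = 0.5)
  mk <- function(seed) cohort_spec(c(2L, 2L), 2L, list(g, g),
                                   roi_size_he_px = 20L, seed = seed)
  generate_cohort(mk(5), dir1)
  generate_cohort(mk(5), dir2)
  generate_cohort(mk(6), dir3)

  # same seed: byte-identical ground truth and images
  expect_identical(readLines(file.path(dir1, "ground_truth_fibers.csv")),
                   readLines(file.path(dir2, "ground_truth_fibers.csv")))
  expect_identical(readBin(file.path(dir1, "G1_C001_shg.tif"), "raw", 1e6),
                   readBin(file.path(dir2, "G1_C001_shg.tif"), "raw", 1e6))

  # different seed: disjoint fiber tables
  f1 <- utils::read.csv(file.path(dir1, "ground_truth_fibers.csv"))
  f3 <- utils::read.csv(file.path(dir3, "ground_truth_fibers.csv"))
  # orientations are continuous draws, so equality across seeds means reuse
  expect_length(intersect(round(f1$orientation_deg, 8),
                          round(f3$orientation_deg, 8)), 0)

  # manifest structure: unique patient ids, one per core, ROIs within 2-3
  cores <- read_manifest(file.path(dir1, "cores.json"))
  pids <- vapply(cores, `[[`, character(1), "patient_id")
  expect_equal(anyDuplicated(pids), 0)
  expect_true(all(vapply(cores, function(c) length(c$rois), integer(1))
                  %in% 2:3))
  expect_error(cohort_spec(c(2L, 2L), 4L, list(g, g)), "2 or 3")
})

test_that("the pipeline is deterministic and structurally sound end to end", {
  cfg <- pipeline_config()
  dir <- small_cohort_dir()
  cores <- read_manifest(file.path(dir, "cores.json"))
  out1 <- run_pipeline(cores, cfg, out_dir = file.path(tempdir(), "run1"),
                       register = FALSE, fit_models = FALSE)
  out2 <- run_pipeline(cores, cfg, out_dir = file.path(tempdir(), "run2"),
                       register = FALSE, fit_models = FALSE)

  # row-count invariant: one row per ROI over retained cores
  n_rois <- sum(vapply(out1$retained, function(c) length(c$rois),
                       integer(1)))
  expect_equal(nrow(out1$table), n_rois)
  expect_length(out1$failures, 0)

  # rerun with the same seeds: byte-identical metrics CSV
  expect_identical(readLines(file.path(tempdir(), "run1", "roi_metrics.csv")),
                   readLines(file.path(tempdir(), "run2", "roi_metrics.csv")))

  # a single-core cohort cannot support the group model
  expect_error(run_pipeline(cores[1], cfg, register = FALSE,
                            fit_models = TRUE),
               "at least 2 patients")
})
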