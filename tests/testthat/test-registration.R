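# Affine algebra, landmark least squares, intensity registration, ROI
# transformation.

test_that("affine transforms compose and invert within the group", {
  t1 <- similarity2d(1.5, 30, 4, -2)
  t2 <- similarity2d(0.8, -10, -1, 7)
  p <- cbind(c(0, 3, -5), c(1, -2, 4))
  expect_equal(affine_apply(affine_compose(t1, t2), p),
               affine_apply(t1, affine_apply(t2, p)))
  ident <- affine_compose(t1, affine_invert(t1))
  expect_equal(ident$A, diag(2), tolerance = 1e-12)
  expect_equal(ident$b, c(0, 0), tolerance = 1e-12)
  expect_error(affine2d(matrix(c(1, 2, 2, 4), 2)), "singular")
})

test_that("landmark registration reproduces exact transforms and least squares", {
  truth <- affine2d(matrix(c(1.2, 0.3, -0.2, 0.9), 2), c(5, -3))
  src <- cbind(c(0, 10, 3, -4), c(0, 2, 9, 5))
  dst <- affine_apply(truth, src)

  # interpolating case: 3 exact pairs give zero residual and the transform
  fit <- register_landmarks(src[1:3, ], dst[1:3, ], model = "affine")
  expect_equal(fit$A, truth$A, tolerance = 1e-10)
  expect_equal(fit$b, truth$b, tolerance = 1e-10)
  expect_equal(attr(fit, "rms"), 0, tolerance = 1e-10)

  # 4 pairs with one perturbed: positive residual, equal to the analytic
  # normal-equations solution computed directly
  dst_p <- dst
  dst_p[4, ] <- dst_p[4, ] + c(1.5, -0.8)
  fit2 <- register_landmarks(src, dst_p, model = "affine")
  X <- cbind(src, 1)
  beta <- solve(crossprod(X), crossprod(X, dst_p))
  expect_equal(fit2$A, t(beta[1:2, ]), tolerance = 1e-10)
  expect_equal(fit2$b, unname(beta[3, ]), tolerance = 1e-10)
  expect_gt(attr(fit2, "rms"), 0)

  # similarity fit recovers an exact similarity from 2 pairs
  struth <- similarity2d(2.858, 4, 12, -7)
  s_src <- cbind(c(0, 50), c(0, 30))
  fit3 <- register_landmarks(s_src, affine_apply(struth, s_src),
                             model = "similarity")
  expect_equal(fit3$A, struth$A, tolerance = 1e-8)

  # underdetermined and degenerate configurations are named errors
  expect_error(register_landmarks(src[1:2, ], dst[1:2, ], model = "affine"),
               "at least 3")
  col_src <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_error(register_landmarks(col_src, col_src + 1, model = "affine"),
               "non-collinear")
})

test_that("k-means segmentation separates tissue from white background", {
  # two-color image: white background with a pink disk
  h <- 60
  img <- array(1, dim = c(h, h, 3))
  g <- expand.grid(y = 1:h, x = 1:h)
  disk <- (g$x - 30)^2 + (g$y - 30)^2 <= 15^2
  for (ch in 1:3) {
    plane <- matrix(1, h, h)
    plane[cbind(g$y[disk], g$x[disk])] <- c(0.94, 0.7, 0.82)[ch]
    img[, , ch] <- plane
  }
  seg <- segment_he_kmeans(img, k = 2, seed = 1)
  expect_equal(seg$tissue_mask, matrix(disk, h, h))

  # all-white image: warning and empty tissue mask
  white <- array(1, dim = c(20, 20, 3))
  expect_warning(seg_w <- segment_he_kmeans(white, k = 2, seed = 1),
                 "distinct colors")
  expect_false(any(seg_w$tissue_mask))

  # generated pseudo-H&E, k = 3: tissue mask covers the fiber footprint
  spec <- synthetic_spec(image_size_px = c(240, 240), fiber_count_mean = 60,
                         length_log_mean_um = log(8), fiber_width_um = 0.5,
                         seed = 4)
  tr <- sample_fiber_population(spec)
  he <- render_pseudo_he_image(tr)
  seg3 <- segment_he_kmeans(he, k = 3, seed = 1)
  # ground-truth footprint: H&E pixels that map inside the core disk
  tmap <- attr(he, "true_transform")
  gh <- expand.grid(y = 0:(dim(he)[1] - 1), x = 0:(dim(he)[2] - 1))
  p <- affine_apply(tmap, cbind(gh$x, gh$y))
  inside <- (p[, 1] - 119.5)^2 + (p[, 2] - 119.5)^2 <= (0.47 * 240)^2
  covered <- seg3$tissue_mask[cbind(gh$y + 1, gh$x + 1)][inside]
  expect_gt(mean(covered), 0.99)
})

test_that("intensity registration is self-consistent and recovers a shift", {
  spec <- synthetic_spec(image_size_px = c(160, 160), fiber_count_mean = 40,
                         length_log_mean_um = log(8), fiber_width_um = 0.5,
                         seed = 21)
  img <- render_shg_image(sample_fiber_population(spec), noise = FALSE)

  # fixed point: registering an image to itself returns identity
  for (model in c("translation", "rigid", "similarity")) {
    fit <- register_intensity(img, img, model = model, pyramid_levels = 2)
    expect_lt(sqrt(sum(fit$transform$b^2)), 0.1)
    expect_equal(fit$transform$A, diag(2), tolerance = 5e-3)
  }

  # known integer shift, translation model
  sh <- matrix(0, 160, 160)
  sh[1:150, 1:148] <- img[11:160, 13:160]  # content moved by (-12, -10)
  fit_t <- register_intensity(img, sh, model = "translation",
                              pyramid_levels = 3)
  expect_equal(fit_t$transform$b, c(12, 10), tolerance = 0.5)
})

test_that("ROI transformation snaps outward and respects geometry", {
  roi <- roi_annotation("r1", 10, 20, 410, 420, space = "he")

  # identity: bounds unchanged
  t_id <- affine2d(model = "similarity")
  r2 <- transform_roi(roi, t_id)
  expect_equal(c(r2$x0, r2$y0, r2$x1, r2$y1), c(10, 20, 410, 420))
  expect_equal(r2$space, "shg")

  # pure pixel-size scale: 400 H&E px maps to ceiling(400 * 0.505/0.1767)
  # = 1143-1144 SHG px wide
  r <- 0.505 / 0.1767
  r3 <- transform_roi(roi_annotation("r2", 0, 0, 400, 400),
                      similarity2d(scale = r))
  expect_equal(r3$x1 - r3$x0, 1144)
  expect_true(r3$x1 - r3$x0 >= floor(400 * r))

  # 90 degree rotation swaps width and height
  wide <- roi_annotation("r3", 0, 0, 300, 100)
  r4 <- transform_roi(wide, similarity2d(1, 90, 0, 0))
  expect_equal(r4$x1 - r4$x0, 100)
  expect_equal(r4$y1 - r4$y0, 300)

  # outward rounding: mapping there and back contains the original
  t <- similarity2d(1.3, 17, 5.2, -3.7)
  fwd <- transform_roi(roi, t)
  back <- transform_roi(fwd, affine_invert(t))
  expect_lte(back$x0, roi$x0)
  expect_lte(back$y0, roi$y0)
  expect_gte(back$x1, roi$x1)
  expect_gte(back$y1, roi$y1)

  # fully outside the target image is an error
  expect_error(
    transform_roi(roi, similarity2d(1, 0, 5000, 5000), shg_size_px = c(100, 100)),
    "outside")
})
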