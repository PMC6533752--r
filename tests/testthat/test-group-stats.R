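# Random-intercept model, boxplot summaries, grade comparison report.

test_that("noiseless balanced data give the exact degenerate fit", {
  tab <- rbind(
    data.frame(patient_id = rep(c("a", "b"), each = 3), g = 0, density = 10),
    data.frame(patient_id = rep(c("c", "d"), each = 3), g = 1, density = 35)
  )
  fit <- fit_random_intercept_model(tab, "density")
  expect_equal(fit$beta0, 10)
  expect_equal(fit$beta1, 25)
  expect_equal(fit$sigma_b, 0)
  expect_equal(fit$sigma_e, 0)
  expect_true(fit$converged)
})

test_that("one observation per patient reduces to two-sample least squares", {
  set.seed(3)
  tab <- simulate_observation_table(25, rois_per_patient = 1L, beta0 = 50,
                                   beta1 = 12, sigma_b = 0, sigma_e = 10,
                                   seed = 31)
  fit <- fit_random_intercept_model(tab, "density")
  ols <- stats::lm(density ~ g, data = tab)
  expect_equal(fit$beta1, unname(stats::coef(ols)["g"]), tolerance = 1e-6)
  expect_equal(fit$beta0, unname(stats::coef(ols)["(Intercept)"]),
               tolerance = 1e-6)
  # variance components are confounded; their sum matches the OLS variance
  expect_equal(fit$sigma_b^2 + fit$sigma_e^2,
               summary(ols)$sigma^2, tolerance = 0.02)
})

test_that("balanced fits equal the difference of per-patient means and are
           location equivariant", {
  tab <- simulate_observation_table(12, 3, beta0 = 100, beta1 = 30,
                                    sigma_b = 15, sigma_e = 20, seed = 77)
  fit <- fit_random_intercept_model(tab, "density")
  pm <- tapply(tab$density, tab$patient_id, mean)
  pg <- tapply(tab$g, tab$patient_id, unique)
  expect_equal(fit$beta1, mean(pm[pg == 1]) - mean(pm[pg == 0]),
               tolerance = 1e-6)
  expect_true(fit$ci95[1] <= fit$beta1 && fit$beta1 <= fit$ci95[2])
  expect_equal(mean(fit$ci95), fit$beta1, tolerance = 1e-9)

  shifted <- tab
  shifted$density <- shifted$density + 500
  fit2 <- fit_random_intercept_model(shifted, "density")
  expect_equal(fit2$beta0, fit$beta0 + 500, tolerance = 1e-6)
  expect_equal(fit2$beta1, fit$beta1, tolerance = 1e-6)
  expect_equal(fit2$sigma_b, fit$sigma_b, tolerance = 1e-5)
  expect_equal(fit2$sigma_e, fit$sigma_e, tolerance = 1e-5)
})

test_that("variance components are recovered on simulated data", {
  fits <- lapply(1:12, function(i) {
    tab <- simulate_observation_table(100, 3, beta0 = 0, beta1 = 40,
                                      sigma_b = 20, sigma_e = 30,
                                      seed = 200 + i)
    fit_random_intercept_model(tab, "density")
  })
  expect_lt(abs(stats::median(vapply(fits, `[[`, numeric(1), "sigma_b")) - 20) / 20,
            0.15)
  expect_lt(abs(stats::median(vapply(fits, `[[`, numeric(1), "sigma_e")) - 30) / 30,
            0.15)
})

test_that("too few patients per group is a clear error", {
  tab <- simulate_observation_table(c(1, 5), 3, seed = 1)
  expect_error(fit_random_intercept_model(tab, "density"),
               "at least 2 patients")
})

test_that("boxplot summaries match brute-force order statistics", {
  # 1..100: median 50.5, quartiles by the type-7 rule, no outliers
  v <- 1:100
  bx <- summarize_boxplot(v)
  expect_equal(bx$median, 50.5)
  expect_equal(bx$q1, unname(stats::quantile(v, 0.25, type = 7)))
  expect_equal(bx$q3, unname(stats::quantile(v, 0.75, type = 7)))
  expect_equal(bx$whisker_low, 1)
  expect_equal(bx$whisker_high, 100)
  expect_length(bx$outliers, 0)

  # constant sample: all summary points equal
  bc <- summarize_boxplot(rep(4.2, 9))
  expect_true(all(c(bc$median, bc$q1, bc$q3, bc$whisker_low,
                    bc$whisker_high) == 4.2))
  expect_length(bc$outliers, 0)

  # IQR 0 with one extreme point: the extreme is an outlier
  bo <- summarize_boxplot(c(rep(0, 20), 1000))
  expect_equal(bo$outliers, 1000)
  expect_equal(bo$whisker_high, 0)
})

test_that("compare_grades reports both outcomes and flags skipped ones", {
  tab <- simulate_observation_table(15, 3, beta0 = 50, beta1 = 25,
                                    sigma_b = 10, sigma_e = 12, seed = 5)
  set.seed(6)
  tab$alignment <- 0.4 + 0.1 * tab$g + stats::rnorm(nrow(tab), 0, 0.05)
  rep1 <- compare_grades(tab)
  expect_gt(rep1$models$density$beta1, 0)
  expect_gt(rep1$models$alignment$beta1, 0)
  expect_false(rep1$partial)
  expect_equal(sort(unique(rep1$boxplots$grade)), c("grade1", "grade4"))
  expect_equal(sum(rep1$counts$n_obs[rep1$counts$outcome == "density"]),
               nrow(tab))

  # one outcome entirely missing: skipped with a note, partial result
  tab$alignment <- NA_real_
  rep2 <- compare_grades(tab)
  expect_true(rep2$partial)
  expect_true(isTRUE(rep2$models$alignment$skipped))
  expect_false(is.null(rep2$models$density$beta1))
})
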