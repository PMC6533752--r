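# Grade-group comparison: linear mixed-effects model with per-patient
# random intercepts, y_ij = beta0 + beta1 * g_i + b_i + e_ij,
# b_i ~ N(0, sigma_b^2), e_ij ~ N(0, sigma_e^2), fit by REML; plus the
# boxplot summary convention used for reporting.

#' Fit the random-intercept grade model
#'
#' REML fit of a linear mixed model with a fixed grade effect and a random
#' intercept per patient, accounting for the within-patient correlation of
#' multiple ROI measurements. Rows with a missing outcome are dropped
#' (listwise, per outcome), so the alignment analysis runs on its reduced
#' sample. The grade contrast is tested two-sided with nlme's
#' between-within degrees of freedom (the grade term is constant within
#' patient, giving `n_patients - 2` df), and the 95% CI is the Wald
#' interval on that t distribution.
#'
#' Perfectly noiseless data (zero variance within and between patients in
#' both groups) makes the likelihood degenerate; that case is detected and
#' returned as the exact closed-form fit with `sigma_b = sigma_e = 0` and a
#' `NA` p-value, flagged in `note`.
#'
#' @param table observation data frame with columns `patient_id`, `g`
#'   (0 = grade 1, 1 = grade 4), and the outcome column.
#' @param outcome `"density"`, `"alignment"`, or `"intensity_fraction"`.
#' @param method `"REML"` (default, the convention for variance-component
#'   estimation in this model class) or `"ML"`.
#' @return an object of class `mixed_model_fit`: `beta0`, `beta1`, `se1`,
#'   `ci95`, `p_value`, `df`, `sigma_b`, `sigma_e`, `n_obs`, `n_patients`,
#'   `converged`, `note`.
#' @export
fit_random_intercept_model <- function(table,
                                       outcome = c("density", "alignment",
                                                   "intensity_fraction"),
                                       method = c("REML", "ML")) {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  d <- table[!is.na(table[[outcome]]), , drop = FALSE]
  d$y <- as.numeric(d[[outcome]])
  d$patient_id <- as.character(d$patient_id)
  per_group <- tapply(d$patient_id, d$g, function(p) length(unique(p)))
  if (length(per_group) < 2 || any(per_group < 2)) {
    stopf("grade comparison needs at least 2 patients per group (got %s)",
          paste(per_group, collapse = "/"))
  }
  n_obs <- nrow(d)
  n_patients <- length(unique(d$patient_id))

  group_means <- tapply(d$y, d$g, mean)
  if (all(tapply(d$y, d$g, stats::var) < 1e-24)) {
    beta1 <- unname(group_means["1"] - group_means["0"])
    return(structure(list(
      beta0 = unname(group_means["0"]), beta1 = beta1, se1 = 0,
      ci95 = c(beta1, beta1), p_value = NA_real_,
      df = n_patients - 2, sigma_b = 0, sigma_e = 0,
      n_obs = n_obs, n_patients = n_patients, converged = TRUE,
      note = "degenerate: zero variance within both groups"
    ), class = "mixed_model_fit"))
  }

  fit <- tryCatch(
    nlme::lme(y ~ g, random = ~ 1 | patient_id, data = d, method = method,
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(
      beta0 = NA_real_, beta1 = NA_real_, se1 = NA_real_,
      ci95 = c(NA_real_, NA_real_), p_value = NA_real_, df = NA_real_,
      sigma_b = NA_real_, sigma_e = NA_real_,
      n_obs = n_obs, n_patients = n_patients, converged = FALSE,
      note = paste("non-convergence:", conditionMessage(fit))
    ), class = "mixed_model_fit"))
  }
  tt <- summary(fit)$tTable
  beta0 <- unname(tt["(Intercept)", "Value"])
  beta1 <- unname(tt["g", "Value"])
  se1 <- unname(tt["g", "Std.Error"])
  df <- unname(tt["g", "DF"])
  p <- unname(tt["g", "p-value"])
  sigma_b <- sqrt(as.numeric(nlme::VarCorr(fit)["(Intercept)", "Variance"]))
  sigma_e <- fit$sigma
  note <- if (sigma_b < 1e-6 * max(sigma_e, 1e-12)) {
    "singular fit: random-intercept variance estimated at the boundary"
  } else {
    NA_character_
  }
  hw <- stats::qt(0.975, df) * se1
  structure(list(
    beta0 = beta0, beta1 = beta1, se1 = se1,
    ci95 = c(beta1 - hw, beta1 + hw), p_value = p, df = df,
    sigma_b = sigma_b, sigma_e = sigma_e,
    n_obs = n_obs, n_patients = n_patients, converged = TRUE, note = note
  ), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("random-intercept model: n_obs=%d, n_patients=%d\n",
              x$n_obs, x$n_patients))
  cat(sprintf("  beta0 = %.4f\n", x$beta0))
  cat(sprintf("  beta1 = %.4f  [95%% CI %.4f, %.4f]  p = %.3g (df = %s)\n",
              x$beta1, x$ci95[1], x$ci95[2], x$p_value, format(x$df)))
  cat(sprintf("  sigma_b = %.4f, sigma_e = %.4f, converged = %s\n",
              x$sigma_b, x$sigma_e, x$converged))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Boxplot summary of a sample
#'
#' The default-boxplot convention: median, first and third quartiles
#' (type-7 sample quantiles), whiskers at the most extreme observations
#' within 1.5 IQR of the quartiles, and the list of points outside the
#' whiskers as outliers.
#'
#' @param values nonempty numeric vector.
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
summarize_boxplot <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stopf("empty sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]),
       n = length(values))
}

#' Compare grade groups on every collagen feature
#'
#' Fits the random-intercept model separately for density and alignment
#' (each on its own non-missing sample), and produces per-group boxplot
#' summaries and observation counts. A feature with no usable observations
#' is skipped with a note rather than failing the report.
#'
#' @param table observation data frame (see [build_observation_table()]).
#' @param config a [pipeline_config()].
#' @param outcomes feature columns to compare.
#' @return list with `models` (per-outcome fit, or a skip note), `boxplots`
#'   (data frame of per group/outcome summaries), `counts` (per-group
#'   observation and patient counts per outcome), and `partial` (`TRUE`
#'   when any outcome was skipped).
#' @export
compare_grades <- function(table, config = pipeline_config(),
                           outcomes = c("density", "alignment")) {
  models <- list()
  boxrows <- list()
  counts <- list()
  partial <- FALSE
  for (oc in outcomes) {
    vals <- table[[oc]]
    ok <- !is.na(vals)
    if (!any(ok)) {
      models[[oc]] <- list(skipped = TRUE,
                           note = sprintf("no non-missing '%s' values", oc))
      partial <- TRUE
      next
    }
    fit <- fit_random_intercept_model(table, oc)
    models[[oc]] <- unclass(fit)
    for (gr in sort(unique(table$grade))) {
      sel <- ok & table$grade == gr
      if (!any(sel)) next
      bx <- summarize_boxplot(vals[sel])
      boxrows[[length(boxrows) + 1]] <- data.frame(
        outcome = oc, grade = gr, n = bx$n, median = bx$median,
        q1 = bx$q1, q3 = bx$q3, whisker_low = bx$whisker_low,
        whisker_high = bx$whisker_high, n_outliers = length(bx$outliers))
      counts[[length(counts) + 1]] <- data.frame(
        outcome = oc, grade = gr, n_obs = sum(sel),
        n_patients = length(unique(table$patient_id[sel])))
    }
  }
  list(models = models,
       boxplots = do.call(rbind, boxrows),
       counts = do.call(rbind, counts),
       partial = partial)
}

#' Simulate an observation table from the random-intercept model
#'
#' Direct model-based simulation (no images) for calibration studies:
#' `y_ij = beta0 + beta1 * g_i + b_i + e_ij` with per-patient intercepts
#' `b_i ~ N(0, sigma_b^2)` and residuals `e_ij ~ N(0, sigma_e^2)`.
#'
#' @param n_per_group patients per grade group (length-2 or scalar).
#' @param rois_per_patient observations per patient.
#' @param beta0,beta1 fixed effects.
#' @param sigma_b,sigma_e standard deviations of the random intercept and
#'   the residual.
#' @param seed integer seed.
#' @return observation data frame with `patient_id`, `grade`, `g`,
#'   `roi_id`, `density` (the simulated outcome).
#' @export
simulate_observation_table <- function(n_per_group, rois_per_patient = 3L,
                                       beta0 = 0, beta1 = 0,
                                       sigma_b = 1, sigma_e = 1,
                                       seed = 1L) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  with_seed(seed, {
    rows <- list()
    pid <- 0L
    for (g in 0:1) {
      for (i in seq_len(n_per_group[g + 1])) {
        pid <- pid + 1L
        b <- stats::rnorm(1, 0, sigma_b)
        y <- beta0 + beta1 * g + b +
          stats::rnorm(rois_per_patient, 0, sigma_e)
        rows[[pid]] <- data.frame(
          patient_id = sprintf("P%04d", pid),
          grade = if (g == 1) "grade4" else "grade1",
          g = g,
          roi_id = sprintf("P%04d_R%d", pid, seq_len(rois_per_patient)),
          density = y)
      }
    }
    do.call(rbind, rows)
  })
}
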