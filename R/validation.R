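#' Stratified country-holdout plan
#'
#' Builds the external-validation design: in each repetition, roughly 10%
#' of the countries with data are withheld, sampled without replacement
#' within each data-availability stratum separately for each sex (fits are
#' sex-stratified). Deterministic given the seed.
#'
#' @param availability Tibble from [availability_table()] (`country`,
#'   `sex`, `stratum`).
#' @param fraction Fraction of countries withheld per repetition.
#'   Default 0.10.
#' @param n_reps Number of repetitions. Default 5.
#' @param seed Integer seed.
#' @return A `holdout_plan`: list with `repetitions` (tibble `rep`, `sex`,
#'   `stratum`, `country`), `fraction`, `n_reps`, `seed`.
#' @export
make_holdout_plan <- function(availability, fraction = 0.10, n_reps = 5,
                              seed = 1) {
  stopifnot(fraction > 0, fraction < 1, n_reps >= 1)
  av <- tibble::as_tibble(availability)
  reps <- with_seed(seed, {
    out <- list()
    for (r in seq_len(n_reps)) {
      for (sx in sort(unique(av$sex))) {
        for (st in sort(unique(av$stratum[av$sex == sx]))) {
          pool <- sort(av$country[av$sex == sx & av$stratum == st])
          m <- length(pool)
          quota <- max(1L, round(fraction * m))
          if (quota > m) {
            warning(sprintf(
              "stratum %s/%s smaller than its quota; reduced to %d",
              st, sx, m))
            quota <- m
          }
          held <- sort(sample(pool, quota))
          out[[length(out) + 1]] <- tibble::tibble(
            rep = r, sex = sx, stratum = st, country = held)
        }
      }
    }
    dplyr::bind_rows(out)
  })
  structure(list(repetitions = reps, fraction = fraction, n_reps = n_reps,
                 seed = seed),
            class = "holdout_plan")
}

#' @export
print.holdout_plan <- function(x, ...) {
  cat(sprintf("holdout plan: %d repetitions, fraction %.2f\n",
              x$n_reps, x$fraction))
  print(dplyr::count(x$repetitions, .data$rep, .data$sex))
  invisible(x)
}

#' Credible-interval coverage
#'
#' Percentage of values falling inside their closed intervals
#' (values exactly on a bound count as covered).
#'
#' @param lo,hi Interval bounds.
#' @param values Held-out values.
#' @return Coverage in percent (0--100).
#' @export
coverage <- function(lo, hi, values) {
  stopifnot(length(lo) == length(hi), length(lo) == length(values))
  if (any(lo > hi)) stop("interval with lo > hi")
  100 * mean(values >= lo & values <= hi)
}

#' Posterior predictions for new observations
#'
#' Predicts study-summary rows from a fitted model. The point estimate is
#' always the posterior mean of the population-level mean height (study
#' offset zero) at the row's cohort and age. In `"observation"` mode the
#' interval is predictive for the observed study mean: each posterior draw
#' adds noise with variance `se^2 + omega^2 + nu^2 + tau^2` for the row's
#' coverage level (zero study components for national rows). In
#' `"population"` mode the interval is on the population mean itself.
#'
#' @param fit A `heightfit`.
#' @param newdata Tibble with `country`, `birth_cohort`, `mid_age`,
#'   `se_cm`, `coverage` (computed via [filter_analysis_set()] if
#'   `birth_cohort` absent).
#' @param mode `"observation"` or `"population"`.
#' @param seed Seed for the predictive noise draws (observation mode).
#' @return Tibble `estimate`, `lo`, `hi` aligned with `newdata` rows.
#' @export
predict_observations <- function(fit, newdata,
                                 mode = c("observation", "population"),
                                 seed = 1) {
  mode <- match.arg(mode)
  nd <- tibble::as_tibble(newdata)
  if (!"birth_cohort" %in% names(nd)) {
    nd$mid_age <- mid_age(nd$age_group)
    nd$birth_cohort <- nd$survey_year - nd$mid_age
  }
  draws <- pooled_draws(fit)
  sc <- draws$scalars
  ndraw <- ncol(sc)
  ci <- match(nd$country, fit$hierarchy$countries)
  if (anyNA(ci)) stop("unknown country in newdata")
  pos <- grid_position(nd$birth_cohort, fit$config)
  k <- length(fit$grid)
  i0 <- pmin(floor(pos), k - 1); w <- pos - i0
  gamma_d <- sc["gamma", ]

  noise <- if (mode == "observation") {
    var_d <- function(level) {
      switch(level,
             national = sc["omega2", ],
             subnational = sc["omega2", ] + sc["nu2_subnational", ] +
               sc["tau2_subnational", ],
             community = sc["omega2", ] + sc["nu2_community", ] +
               sc["tau2_community", ])
    }
    with_seed(seed, {
      vapply(seq_len(nrow(nd)), function(r) {
        stats::rnorm(ndraw, 0, sqrt(nd$se_cm[r]^2 + var_d(nd$coverage[r])))
      }, numeric(ndraw))
    })
  } else NULL

  out <- lapply(seq_len(nrow(nd)), function(r) {
    curve_d <- draws$curves[ci[r], i0[r], ] * (1 - w[r]) +
      draws$curves[ci[r], i0[r] + 1, ] * w[r]
    mu_d <- curve_d + gamma_d * (nd$mid_age[r] - 18)
    pred_d <- if (is.null(noise)) mu_d else mu_d + noise[, r]
    c(mean(mu_d), qtl(pred_d, 0.025), qtl(pred_d, 0.975))
  })
  out <- do.call(rbind, out)
  tibble::tibble(estimate = out[, 1], lo = out[, 2], hi = out[, 3])
}

#' Holdout error metrics
#'
#' The per-subset summary used by the holdout validation: median error,
#' 25th/75th percentile errors, median absolute error, and 95% interval
#' coverage. Quantiles use linear interpolation between order statistics.
#'
#' @param errors Numeric vector of (estimate - held-out value) errors.
#' @param covered Logical vector: value inside its 95% interval.
#' @return One-row tibble: `n`, `median_error`, `q25_error`, `q75_error`,
#'   `median_abs_error`, `coverage_pct`.
#' @export
error_summary <- function(errors, covered) {
  tibble::tibble(n = length(errors),
                 median_error = stats::median(errors),
                 q25_error = qtl(errors, 0.25),
                 q75_error = qtl(errors, 0.75),
                 median_abs_error = stats::median(abs(errors)),
                 coverage_pct = 100 * mean(covered))
}

#' Run the stratified holdout validation
#'
#' For each repetition and sex, refits the model with the held-out
#' countries' data removed (the countries stay in the hierarchy, so their
#' estimates borrow strength from their region, exactly as for a country
#' with no data), predicts every held-out observation at its actual cohort
#' and age, and scores errors and interval coverage.
#'
#' @param observations Filtered observation tibble (both sexes).
#' @param hierarchy A `country_index`.
#' @param plan A `holdout_plan`.
#' @param config A `height_model_config`.
#' @param mcmc An `mcmc_config` (short chains are customary here).
#' @param mode `"observation"` (score against held-out observed means, with
#'   observation-level predictive intervals) or `"truth"` (score against a
#'   synthetic truth surface at age 18; population-level intervals).
#' @param truth For `"truth"` mode, a list of `truth_surface`s by sex.
#' @return A `holdout_report`: list with `detail` (one row per held-out
#'   observation), `by_rep` (metrics per stratum x sex x repetition),
#'   `by_subset` (per stratum x sex, pooled over repetitions), and
#'   `global` (per sex and overall).
#' @export
run_holdout <- function(observations, hierarchy, plan,
                        config = model_config(), mcmc = mcmc_config(),
                        mode = c("observation", "truth"), truth = NULL) {
  mode <- match.arg(mode)
  if (mode == "truth" && is.null(truth)) stop("truth mode needs surfaces")
  obs <- tibble::as_tibble(observations)
  if (!"birth_cohort" %in% names(obs)) {
    obs$mid_age <- mid_age(obs$age_group)
    obs$birth_cohort <- obs$survey_year - obs$mid_age
  }

  details <- list()
  for (r in seq_len(plan$n_reps)) {
    for (sx in sort(unique(plan$repetitions$sex))) {
      held <- plan$repetitions[plan$repetitions$rep == r &
                                 plan$repetitions$sex == sx, ]
      if (nrow(held) == 0) next
      sex_obs <- obs[obs$sex == sx, ]
      train <- sex_obs[!sex_obs$country %in% held$country, ]
      test <- sex_obs[sex_obs$country %in% held$country, ]
      if (nrow(test) == 0) next
      mc <- mcmc
      mc$seed <- mcmc$seed + 100 * r + 10 * match(sx, c("female", "male"))
      f <- fit(train, hierarchy, config, mc)
      pred <- predict_observations(
        f, test,
        mode = if (mode == "observation") "observation" else "population",
        seed = mc$seed + 1)
      target <- if (mode == "observation") test$mean_cm else
        truth_height(truth[[sx]], test$country, test$birth_cohort)
      details[[length(details) + 1]] <- tibble::tibble(
        rep = r, sex = sx,
        stratum = held$stratum[match(test$country, held$country)],
        country = test$country, study_id = test$study_id,
        birth_cohort = test$birth_cohort,
        observed = target, estimate = pred$estimate,
        lo = pred$lo, hi = pred$hi,
        error = pred$estimate - target,
        covered = target >= pred$lo & target <= pred$hi)
    }
  }
  detail <- dplyr::bind_rows(details)

  metrics <- function(d, ...) {
    dplyr::reframe(dplyr::group_by(d, ...),
                   error_summary(.data$error, .data$covered))
  }
  structure(list(
    detail = detail,
    by_rep = metrics(detail, .data$stratum, .data$sex, .data$rep),
    by_subset = metrics(detail, .data$stratum, .data$sex),
    global = dplyr::bind_rows(metrics(detail, .data$sex),
                              metrics(detail)),
    mode = mode, plan = plan
  ), class = "holdout_report")
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf("holdout validation (%s mode): %d held-out observations\n",
              x$mode, nrow(x$detail)))
  print(x$by_subset)
  cat("global:\n")
  print(x$global)
  invisible(x)
}

#' Write a holdout report to disk
#'
#' Writes `holdout_report.csv` (per-subset metrics) and a JSON summary with
#' the pooled global rows.
#'
#' @param report A `holdout_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_holdout_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$by_rep, file.path(dir, "holdout_report.csv"))
  jsonlite::write_json(
    list(mode = report$mode,
         by_subset = report$by_subset, global = report$global),
    file.path(dir, "holdout_summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
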