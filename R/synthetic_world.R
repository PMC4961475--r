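#' Ground-truth generative parameters
#'
#' Parameters of the synthetic truth surface: a world line (anchored at the
#' 1896 cohort), normal intercept/slope deviations at super-region, region
#' and country level, constrained RW2 non-linear components at all four
#' levels, a linear age-drift slope, and the systematic-offset and
#' extra-variance magnitudes of non-national sources.
#'
#' Sex-specific defaults place the world mean at 163 cm (men) / 152 cm
#' (women) for the 1896 cohort with century gains averaging ~10 cm (men) /
#' ~9 cm (women) and a cross-country range of roughly 20 cm, and use age
#' drifts of -0.02 (men) / -0.03 (women) cm per year of age.
#'
#' @param sex `"male"` or `"female"` (selects defaults).
#' @param world_intercept Mean height (cm) of the world line at cohort 1896.
#' @param world_slope World linear trend (cm per cohort year).
#' @param sd_intercept Named SDs (cm) of intercept deviations:
#'   super, region, country.
#' @param sd_slope Named SDs (cm/yr) of slope deviations.
#' @param rw2_sd Named RW2 innovation SDs (cm per 1-year step):
#'   world, super, region, country.
#' @param age_slope Height change per year of age beyond 18 (cm, <= 0).
#' @param bias_sd Named SDs (cm) of study offsets: subnational, community.
#' @param extra_sd Named extra residual SDs (cm): subnational, community.
#' @return A `truth_params` list.
#' @export
truth_params <- function(sex = c("male", "female"),
                         world_intercept = NULL, world_slope = NULL,
                         sd_intercept = c(super = 4, region = 2.5,
                                          country = 1.5),
                         sd_slope = c(super = 0.03, region = 0.02,
                                      country = 0.025),
                         rw2_sd = c(world = 0.015, super = 0.01,
                                    region = 0.01, country = 0.015),
                         age_slope = NULL,
                         bias_sd = c(subnational = 1.0, community = 1.5),
                         extra_sd = c(subnational = 0.5, community = 1.0)) {
  sex <- match.arg(sex)
  if (is.null(world_intercept)) {
    world_intercept <- if (sex == "male") 163 else 152
  }
  if (is.null(world_slope)) world_slope <- if (sex == "male") 0.10 else 0.09
  if (is.null(age_slope)) age_slope <- if (sex == "male") -0.02 else -0.03
  if (age_slope > 0) stop("age_slope must be <= 0")
  structure(list(sex = sex, world_intercept = world_intercept,
                 world_slope = world_slope, sd_intercept = sd_intercept,
                 sd_slope = sd_slope, rw2_sd = rw2_sd,
                 age_slope = age_slope, bias_sd = bias_sd,
                 extra_sd = extra_sd),
            class = "truth_params")
}

#' Simulate a ground-truth height surface
#'
#' Draws, for one sex, the true mean height at age 18 for every country and
#' integer birth cohort 1896--1996: world line plus hierarchical intercept
#' and slope deviations plus constrained RW2 components at world,
#' super-region, region and country level.
#'
#' @param hierarchy A `country_index`.
#' @param params A `truth_params`.
#' @param seed Integer seed; the same seed reproduces the same surface.
#' @param t0 Centering cohort for slope deviations. Default 1946.
#' @return A `truth_surface`: list with `hierarchy`, `sex`, `cohorts`
#'   (1896:1996), `height18` (country x cohort matrix, cm), `age_slope`,
#'   `bias_sd`, `extra_sd`, and the drawn `components`.
#' @export
simulate_truth <- function(hierarchy, params, seed = 1, t0 = 1946) {
  h <- validate_hierarchy(hierarchy)
  cohorts <- 1896:1996
  k <- length(cohorts)
  nC <- length(h$countries); nR <- length(h$regions)
  nS <- length(h$super_regions)

  comp <- with_seed(seed, {
    draw <- function(n, sd) stats::rnorm(n, 0, sd)
    rw_mat <- function(n, sd) {
      vapply(seq_len(n), function(i) rw2_simulate(k, sd), numeric(k))
    }
    list(alpha_g = stats::setNames(draw(nS, params$sd_intercept[["super"]]),
                                   h$super_regions),
         alpha_r = stats::setNames(draw(nR, params$sd_intercept[["region"]]),
                                   h$regions),
         alpha_c = stats::setNames(draw(nC, params$sd_intercept[["country"]]),
                                   h$countries),
         beta_g = stats::setNames(draw(nS, params$sd_slope[["super"]]),
                                  h$super_regions),
         beta_r = stats::setNames(draw(nR, params$sd_slope[["region"]]),
                                  h$regions),
         beta_c = stats::setNames(draw(nC, params$sd_slope[["country"]]),
                                  h$countries),
         u_glob = rw2_simulate(k, params$rw2_sd[["world"]]),
         u_g = rw_mat(nS, params$rw2_sd[["super"]]),
         u_r = rw_mat(nR, params$rw2_sd[["region"]]),
         u_c = rw_mat(nC, params$rw2_sd[["country"]]))
  })

  reg <- match(h$region_of[h$countries], h$regions)
  sup <- match(h$super_region_of[h$regions], h$super_regions)[reg]
  world <- params$world_intercept + params$world_slope * (cohorts - 1896)
  height18 <- matrix(NA_real_, nC, k, dimnames = list(h$countries, cohorts))
  for (i in seq_len(nC)) {
    level <- comp$alpha_g[sup[i]] + comp$alpha_r[reg[i]] + comp$alpha_c[i]
    slope <- comp$beta_g[sup[i]] + comp$beta_r[reg[i]] + comp$beta_c[i]
    height18[i, ] <- world + level + slope * (cohorts - t0) + comp$u_glob +
      comp$u_g[, sup[i]] + comp$u_r[, reg[i]] + comp$u_c[, i]
  }
  if (!all(is.finite(height18))) stop("non-finite truth surface")

  structure(list(hierarchy = h, sex = params$sex, cohorts = cohorts,
                 height18 = height18, age_slope = params$age_slope,
                 bias_sd = params$bias_sd, extra_sd = params$extra_sd,
                 params = params, components = comp),
            class = "truth_surface")
}

#' True mean height at age 18
#'
#' Looks up the truth surface at (possibly half-integer) cohorts by linear
#' interpolation; cohorts beyond the grid edges are extrapolated with the
#' edge slope (such rows are dropped by the analysis-set filter anyway).
#'
#' @param truth A `truth_surface`.
#' @param country Country code(s).
#' @param cohort Cohort value(s).
#' @return Numeric vector of true heights (cm).
#' @export
truth_height <- function(truth, country, cohort) {
  n <- max(length(country), length(cohort))
  country <- rep_len(country, n); cohort <- rep_len(cohort, n)
  i <- match(country, rownames(truth$height18))
  if (anyNA(i)) stop("unknown country in truth surface")
  k <- length(truth$cohorts)
  pos <- cohort - truth$cohorts[1] + 1
  out <- numeric(n)
  for (r in seq_len(n)) {
    row <- truth$height18[i[r], ]
    p <- pos[r]
    if (p < 1) {
      out[r] <- row[1] + (p - 1) * (row[2] - row[1])
    } else if (p > k) {
      out[r] <- row[k] + (p - k) * (row[k] - row[k - 1])
    } else {
      out[r] <- interp_grid(row, p)
    }
  }
  out
}

#' Survey-database design
#'
#' Composition of the synthetic survey database: how many studies each
#' country contributes, the national/subnational/community mix (default the
#' real-world 54/14/32 percent composition), survey years, age-group
#' coverage, per-cell sample sizes, and the within-age-group SD of
#' individual heights from which sampling SEs derive.
#'
#' @param studies_per_country `c(min, max)` of the per-country study count.
#' @param studies_per_country_skew Skew of the study-count distribution:
#'   counts k are drawn with probability proportional to `k^-skew` (0 =
#'   uniform). The default 1 makes survey-poor countries common, as in real
#'   pooled databases, so all three data-availability strata are populated.
#' @param coverage_probs Named probabilities over national, subnational,
#'   community; must sum to 1.
#' @param year_range `c(first, last)` survey years, drawn uniformly.
#' @param age_groups Age groups available to studies.
#' @param p_full_age_range Probability a study reports all age groups;
#'   otherwise a contiguous run of `partial_run` groups is reported.
#' @param partial_run `c(min, max)` length of partial age-group runs.
#' @param n_meanlog,n_sdlog Log-normal parameters of per-cell sample sizes.
#' @param n_min,n_max Truncation of per-cell sample sizes.
#' @param within_sd_cm Within-age-group SD of individual heights (cm);
#'   the sampling SE of a cell mean is `within_sd_cm / sqrt(n)`.
#' @param sex_probs Named probabilities a study measures both sexes, men
#'   only, or women only.
#' @return A `survey_design` list.
#' @export
survey_design <- function(studies_per_country = c(min = 3, max = 30),
                          studies_per_country_skew = 1,
                          coverage_probs = c(national = 0.54,
                                             subnational = 0.14,
                                             community = 0.32),
                          year_range = c(1960, 2014),
                          age_groups = standard_age_groups(),
                          p_full_age_range = 0.3,
                          partial_run = c(min = 1, max = 4),
                          n_meanlog = log(400), n_sdlog = 0.7,
                          n_min = 25, n_max = 5000,
                          within_sd_cm = 7,
                          sex_probs = c(both = 0.76, male = 0.10,
                                        female = 0.14)) {
  if (abs(sum(coverage_probs) - 1) > 1e-8) {
    stop("coverage_probs must sum to 1")
  }
  structure(list(studies_per_country = studies_per_country,
                 studies_per_country_skew = studies_per_country_skew,
                 coverage_probs = coverage_probs, year_range = year_range,
                 age_groups = age_groups,
                 p_full_age_range = p_full_age_range,
                 partial_run = partial_run,
                 n_meanlog = n_meanlog, n_sdlog = n_sdlog,
                 n_min = n_min, n_max = n_max,
                 within_sd_cm = within_sd_cm, sex_probs = sex_probs),
            class = "survey_design")
}

#' Simulate a survey database from truth surfaces
#'
#' Generates study-level summary rows: each study draws a coverage level, a
#' survey year and an age-group span; non-national studies draw systematic
#' offsets (per sex) and carry extra residual variance. Each emitted mean is
#' the true height at the row's birth cohort plus the age-drift term, the
#' study offset, and noise with variance `se^2 + extra_sd^2`.
#'
#' @param truths A single `truth_surface` or a list of them (one per sex
#'   with matching hierarchies).
#' @param design A `survey_design`.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return Observation tibble in the `observations.csv` schema.
#' @export
simulate_studies <- function(truths, design, seed = 1) {
  if (inherits(truths, "truth_surface")) truths <- list(truths)
  names(truths) <- vapply(truths, function(tr) tr$sex, character(1))
  h <- truths[[1]]$hierarchy
  for (tr in truths) stopifnot(identical(tr$hierarchy$countries, h$countries))

  rows <- with_seed(seed, {
    out <- vector("list", 4096L); nout <- 0L
    for (ci in seq_along(h$countries)) {
      country <- h$countries[ci]
      counts <- design$studies_per_country[["min"]]:
        design$studies_per_country[["max"]]
      skew <- design$studies_per_country_skew %||% 0
      n_st <- sample1(counts, prob = counts^(-skew))
      for (s in seq_len(n_st)) {
        study_id <- sprintf("%s_S%02d", country, s)
        year <- sample1(design$year_range[1]:design$year_range[2])
        coverage <- sample1(names(design$coverage_probs),
                            prob = design$coverage_probs)
        scope <- switch(coverage,
                        national = "mixed",
                        subnational = "mixed",
                        community = sample(c("urban", "rural"), 1))
        groups <- design$age_groups
        if (stats::runif(1) > design$p_full_age_range &&
            length(groups) > design$partial_run[["min"]]) {
          len <- sample1(design$partial_run[["min"]]:
                           min(design$partial_run[["max"]], length(groups)))
          start <- sample1(seq_len(length(groups) - len + 1))
          groups <- groups[start:(start + len - 1)]
        }
        sex_mode <- sample(names(design$sex_probs), 1,
                           prob = design$sex_probs)
        sexes <- switch(sex_mode, both = c("male", "female"),
                        male = "male", female = "female")
        sexes <- intersect(sexes, names(truths))
        for (sex in sexes) {
          tr <- truths[[sex]]
          offset <- if (coverage == "national") 0 else
            stats::rnorm(1, 0, tr$bias_sd[[coverage]])
          extra <- if (coverage == "national") 0 else
            tr$extra_sd[[coverage]]
          mids <- mid_age(groups)
          cohorts <- year - mids
          n_cell <- pmin(pmax(round(stats::rlnorm(length(groups),
                                                  design$n_meanlog,
                                                  design$n_sdlog)),
                              design$n_min), design$n_max)
          se <- design$within_sd_cm / sqrt(n_cell)
          mu <- truth_height(tr, country, cohorts) +
            tr$age_slope * (mids - 18) + offset
          y <- stats::rnorm(length(mu), mu, sqrt(se^2 + extra^2))
          nout <- nout + 1L
          if (nout > length(out)) out <- c(out, vector("list", length(out)))
          out[[nout]] <- tibble::tibble(
            study_id = study_id, country = country, sex = sex,
            coverage = coverage, scope = scope, survey_year = year,
            age_group = groups, mean_cm = y, se_cm = se, n = n_cell,
            measured = TRUE)
        }
      }
    }
    dplyr::bind_rows(out[seq_len(nout)])
  })
  rows
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper: hierarchy, sex-specific truth surfaces, and the
#' survey database, all derived deterministically from one seed.
#'
#' @param n_countries,n_regions,n_super_regions Hierarchy sizes.
#' @param design A `survey_design`.
#' @param params_male,params_female `truth_params` for each sex.
#' @param seed Integer seed.
#' @return List with `hierarchy`, `truth` (list `male`/`female`) and
#'   `observations`.
#' @export
simulate_world <- function(n_countries = 60, n_regions = 12,
                           n_super_regions = 4,
                           design = survey_design(),
                           params_male = truth_params("male"),
                           params_female = truth_params("female"),
                           seed = 1) {
  h <- make_hierarchy(n_countries, n_regions, n_super_regions, seed = seed)
  truth_m <- simulate_truth(h, params_male, seed = seed + 1)
  truth_f <- simulate_truth(h, params_female, seed = seed + 2)
  obs <- simulate_studies(list(truth_m, truth_f), design, seed = seed + 3)
  list(hierarchy = h, truth = list(male = truth_m, female = truth_f),
       observations = obs)
}

#' Write a synthetic world to disk
#'
#' Writes `observations.csv` (survey schema) and `truth.csv`
#' (country, sex, cohort, height18_cm).
#'
#' @param world Output of [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_observations(world$observations, file.path(dir, "observations.csv"))
  truth_long <- dplyr::bind_rows(lapply(world$truth, function(tr) {
    tibble::tibble(country = rep(rownames(tr$height18),
                                 times = length(tr$cohorts)),
                   sex = tr$sex,
                   cohort = rep(tr$cohorts, each = nrow(tr$height18)),
                   height18_cm = as.vector(tr$height18))
  }))
  readr::write_csv(truth_long, file.path(dir, "truth.csv"))
  invisible(dir)
}
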