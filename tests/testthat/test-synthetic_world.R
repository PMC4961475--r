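test_that("hierarchy generation is balanced, nested and deterministic", {
  h <- make_hierarchy(4, 2, 1, seed = 9)
  expect_equal(sort(as.vector(table(h$region_of))), c(2L, 2L))
  expect_equal(unname(h$super_region_of), rep("S1", 2))
  validate_hierarchy(h)

  h1 <- make_hierarchy(1, 1, 1, seed = 1)
  expect_equal(h1$countries, "C001")
  expect_equal(unname(h1$region_of), "R01")

  expect_identical(make_hierarchy(20, 5, 2, seed = 4),
                   make_hierarchy(20, 5, 2, seed = 4))
  expect_false(identical(make_hierarchy(20, 5, 2, seed = 4),
                         make_hierarchy(20, 5, 2, seed = 5)))
  expect_error(make_hierarchy(2, 3, 1), "n_countries")
})

test_that("degenerate truth parameters give exactly linear surfaces", {
  h <- make_hierarchy(6, 3, 2, seed = 2)
  zero_sd <- truth_params("male", world_intercept = 160, world_slope = 0.05,
                          sd_intercept = c(super = 0, region = 0,
                                           country = 0),
                          sd_slope = c(super = 0, region = 0, country = 0),
                          rw2_sd = c(world = 0, super = 0, region = 0,
                                     country = 0))
  tr <- simulate_truth(h, zero_sd, seed = 1)
  expected <- 160 + 0.05 * (tr$cohorts - 1896)
  for (i in seq_len(6)) {
    expect_equal(unname(tr$height18[i, ]), expected)
  }

  # RW2 off but deviations on: every country curve exactly linear
  lin <- truth_params("male", rw2_sd = c(world = 0, super = 0, region = 0,
                                         country = 0))
  tr2 <- simulate_truth(h, lin, seed = 3)
  for (i in seq_len(6)) {
    expect_equal(max(abs(diff(tr2$height18[i, ], differences = 2))), 0,
                 tolerance = 1e-10)
  }
})

test_that("country intercept deviations match their generative SD", {
  # many draws of a 1-super-region, 1-region world isolate the country
  # level; compare the sample SD against the stated generative value
  h <- make_hierarchy(50, 1, 1, seed = 7)
  pars <- truth_params("male",
                       sd_intercept = c(super = 0, region = 0, country = 2),
                       sd_slope = c(super = 0, region = 0, country = 0),
                       rw2_sd = c(world = 0, super = 0, region = 0,
                                  country = 0))
  devs <- unlist(lapply(1:5, function(s) {
    tr <- simulate_truth(h, pars, seed = s)
    tr$height18[, "1946"] - mean(tr$height18[, "1946"])
  }))
  expect_length(devs, 250)
  # chi-squared MC bounds for sd of 250 normals with sd 2
  expect_gt(stats::sd(devs), 2 * sqrt(stats::qchisq(0.0005, 249) / 249))
  expect_lt(stats::sd(devs), 2 * sqrt(stats::qchisq(0.9995, 249) / 249))
})

test_that("noise-free surveys reproduce truth plus the age term", {
  h <- make_hierarchy(3, 1, 1, seed = 5)
  pars <- truth_params("male")
  tr <- simulate_truth(h, pars, seed = 8)
  des <- survey_design(studies_per_country = c(min = 2, max = 2),
                       coverage_probs = c(national = 1, subnational = 0,
                                          community = 0),
                       within_sd_cm = 1e-9, p_full_age_range = 1,
                       sex_probs = c(both = 1, male = 0, female = 0))
  obs <- simulate_studies(tr, des, seed = 6)
  expected <- truth_height(tr, obs$country,
                           obs$survey_year - mid_age(obs$age_group)) +
    tr$age_slope * (mid_age(obs$age_group) - 18)
  expect_equal(obs$mean_cm, expected, tolerance = 1e-6)
})

test_that("age-drift arithmetic matches the stated mean function", {
  # a 40-49 group at truth 170 with slope -0.02 measures 169.47
  expect_equal(170 + (-0.02) * (mid_age("40-49") - 18), 169.47)
})

test_that("coverage-level mix matches its design probabilities", {
  h <- make_hierarchy(40, 8, 2, seed = 1)
  tr <- simulate_truth(h, truth_params("male"), seed = 2)
  des <- survey_design(studies_per_country = c(min = 25, max = 25),
                       sex_probs = c(both = 1, male = 0, female = 0))
  obs <- simulate_studies(tr, des, seed = 3)
  studies <- dplyr::distinct(obs, study_id, coverage)
  n <- nrow(studies)
  expect_gte(n, 1000)
  p <- c(national = 0.54, subnational = 0.14, community = 0.32)
  for (lv in names(p)) {
    phat <- mean(studies$coverage == lv)
    se <- sqrt(p[[lv]] * (1 - p[[lv]]) / n)
    expect_lt(abs(phat - p[[lv]]), 3 * se)
  }
})

test_that("identical seeds reproduce identical worlds", {
  w1 <- small_world(seed = 13)
  w2 <- small_world(seed = 13)
  expect_identical(w1$observations, w2$observations)
  expect_identical(w1$truth$male$height18, w2$truth$male$height18)
  w3 <- small_world(seed = 14)
  expect_false(identical(w1$observations, w3$observations))
})

test_that("emitted observations pass the analysis filter when in-window", {
  w <- small_world(seed = 21)
  res <- filter_analysis_set(w$observations)
  bc <- birth_cohort(w$observations$survey_year, w$observations$age_group)
  in_window <- bc >= 1896 & bc <= 1996
  expect_equal(nrow(res$retained), sum(in_window))
  expect_true(all(res$excluded$reason == "cohort before 1896"))
  validate_observations(w$observations)
})

test_that("replicate study means scatter as sqrt(se^2 + extra_sd^2)", {
  h <- make_hierarchy(1, 1, 1, seed = 2)
  pars <- truth_params("male",
                       sd_intercept = c(super = 0, region = 0, country = 0),
                       sd_slope = c(super = 0, region = 0, country = 0),
                       rw2_sd = c(world = 0, super = 0, region = 0,
                                  country = 0),
                       bias_sd = c(subnational = 0, community = 0),
                       extra_sd = c(subnational = 0, community = 1.0))
  tr <- simulate_truth(h, pars, seed = 2)
  des <- survey_design(studies_per_country = c(min = 40, max = 40),
                       coverage_probs = c(national = 0, subnational = 0,
                                          community = 1),
                       p_full_age_range = 1,
                       sex_probs = c(both = 1, male = 0, female = 0),
                       n_meanlog = log(400), n_sdlog = 0)
  obs <- dplyr::bind_rows(lapply(1:12, function(s) {
    simulate_studies(tr, des, seed = 100 + s)
  }))
  obs <- obs[obs$age_group == "18", ]
  resid <- obs$mean_cm - truth_height(tr, obs$country,
                                      obs$survey_year - 18)
  target <- sqrt(mean(obs$se_cm^2) + 1.0^2)
  n <- length(resid)
  expect_gt(n, 300)
  expect_gt(stats::sd(resid),
            target * sqrt(stats::qchisq(0.0005, n - 1) / (n - 1)))
  expect_lt(stats::sd(resid),
            target * sqrt(stats::qchisq(0.9995, n - 1) / (n - 1)))
})
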