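test_that("mid-age follows the closed-interval convention", {
  expect_equal(mid_age("18"), 18)
  expect_equal(mid_age("19"), 19)
  expect_equal(mid_age("20-29"), 24.5)
  expect_equal(mid_age("20–29"), 24.5) # en dash accepted
  expect_equal(mid_age("70-79"), 74.5)
  expect_equal(mid_age("80+"), 85)
  expect_equal(mid_age("80+", open_end_mid = 82), 82)
  expect_error(mid_age("17-25"), "17-25")
})

test_that("birth cohort is survey year minus mid-age", {
  expect_equal(birth_cohort(2000, "20-29"), 1975.5)
  expect_equal(birth_cohort(1914, "18"), 1896)
  expect_equal(birth_cohort(2014, "18"), 1996)
  expect_error(birth_cohort(2000, "banana"))
})

test_that("birth cohort is monotone in survey year and mid-age", {
  years <- 1950:2010
  for (ag in standard_age_groups()) {
    expect_true(all(diff(birth_cohort(years, ag)) > 0))
  }
  mids <- mid_age(standard_age_groups())
  expect_true(all(diff(birth_cohort(2000, standard_age_groups())[
    order(mids)]) < 0))
})

make_filter_obs <- function() {
  tibble::tibble(
    study_id = c("a", "b", "c", "d"),
    country = "C001", sex = "male", coverage = "national", scope = "mixed",
    survey_year = c(2000, 2000, 1930, 2010),
    age_group = c("30-39", "30-39", "60-69", "18"),
    mean_cm = c(171, 171, 168, 123),
    se_cm = 0.5, n = 100,
    measured = c(TRUE, FALSE, TRUE, TRUE))
}

test_that("analysis-set filter applies the inclusion rules with a log", {
  res <- filter_analysis_set(make_filter_obs())
  expect_equal(res$retained$study_id, c("a", "d"))
  expect_equal(res$excluded$reason,
               c("self-reported", "cohort before 1896"))
  expect_equal(res$excluded$row, c(2L, 3L))
  # 1930 survey of 60-69 group: cohort 1865.5, before the window
  expect_equal(birth_cohort(1930, "60-69"), 1865.5)
  # no exclusion on the level of height: the 123 cm row is retained
  expect_true("d" %in% res$retained$study_id)
})

test_that("analysis-set filter is idempotent and handles empty input", {
  res1 <- filter_analysis_set(make_filter_obs())
  res2 <- filter_analysis_set(res1$retained)
  expect_equal(res2$retained, res1$retained)
  expect_equal(nrow(res2$excluded), 0)
  res0 <- filter_analysis_set(make_filter_obs()[0, ])
  expect_equal(nrow(res0$retained), 0)
  expect_equal(nrow(res0$excluded), 0)
})

test_that("duplicate flagging groups same country-year sources", {
  src <- tibble::tibble(study_id = c("A", "B", "C"),
                        country = c("X", "X", "X"),
                        survey_year = c(1990, 1990, 1991))
  fl <- flag_duplicates(src)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$group_size, 2)
  expect_equal(fl$study_ids[[1]], c("A", "B"))

  src2 <- tibble::tibble(study_id = c("A", "B"), country = "X",
                         survey_year = c(1990, 1995))
  expect_equal(nrow(flag_duplicates(src2)), 0)
  # same year in different countries is not a duplicate
  src3 <- tibble::tibble(study_id = c("A", "B"), country = c("X", "Y"),
                         survey_year = 1990)
  expect_equal(nrow(flag_duplicates(src3)), 0)
})

test_that("availability classification reproduces the stated thresholds", {
  rich <- c(1900 + 1:24, 1961 + 1:6) # 30 cohorts, 6 after 1960
  expect_equal(classify_data_availability(rich, "male"), "data_rich")
  expect_equal(classify_data_availability(rich, "female"), "data_rich")

  late3 <- c(1900 + 1:27, 1961 + 1:3) # 30 cohorts, 3 after 1960
  expect_equal(classify_data_availability(late3, "male"), "average")

  twelve <- 1900 + 1:12
  expect_equal(classify_data_availability(twelve, "female"), "data_poor")
  expect_equal(classify_data_availability(twelve, "male"), "average")
  eight <- 1900 + 1:8
  expect_equal(classify_data_availability(eight, "male"), "data_poor")
  expect_equal(classify_data_availability(1900 + 1:13, "female"), "average")
  expect_equal(classify_data_availability(1900 + 1:25, "male"), "average")
})

test_that("availability labels partition all counts 1..150", {
  for (sex in c("male", "female")) {
    for (n in 1:150) {
      for (n_late in unique(c(0, min(n, 4), min(n, 5), n))) {
        cohorts <- c(1800 + seq_len(n - n_late),
                     1960.5 + seq_len(n_late))
        lab <- classify_data_availability(cohorts, sex)
        expect_true(lab %in% c("data_rich", "data_poor", "average"))
        # re-derive from the quoted rule
        expected <- if (n > 25) {
          if (n_late >= 5) "data_rich" else "average"
        } else if (n <= (if (sex == "female") 12 else 8)) {
          "data_poor"
        } else "average"
        expect_equal(lab, expected)
      }
    }
  }
})

test_that("observation tables round-trip through CSV with validation", {
  obs <- tiny_obs()[, c("study_id", "country", "sex", "coverage", "scope",
                        "survey_year", "age_group", "mean_cm", "se_cm",
                        "n", "measured")]
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(as.data.frame(back), as.data.frame(obs))

  bad <- obs; bad$se_cm[1] <- 0
  expect_error(validate_observations(bad), "se_cm")
  bad <- obs; bad$sex[1] <- "other"
  expect_error(validate_observations(bad), "sex")
  bad <- obs; bad$mean_cm[1] <- 90
  expect_error(validate_observations(bad), "mean_cm")
})
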