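#' Standard age-group labels
#'
#' The standard age groups used for survey summaries of adult height:
#' single years 18 and 19, the 20--29 decade, then ten-year groups up to
#' 70--79, and the open-ended 80+ group.
#'
#' @return Character vector of the nine standard labels.
#' @export
standard_age_groups <- function() {
  c("18", "19", "20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
}

# Accept both ASCII hyphen and en dash in range labels.
normalize_age_group <- function(age_group) {
  gsub("–", "-", as.character(age_group))
}

#' Mid-age of a standard age group
#'
#' Single-year groups return the year itself; ten-year groups are treated as
#' closed integer ranges with midpoint (lo + hi) / 2 (so "20-29" -> 24.5);
#' the open-ended "80+" group uses a fixed convention (default 85, the
#' midpoint of a symmetric 80--90 span).
#'
#' @param age_group Character vector of labels from [standard_age_groups()]
#'   (en dash accepted in place of the hyphen).
#' @param open_end_mid Mid-age convention for "80+". Default 85.
#' @return Numeric vector of mid-ages in years.
#' @export
#' @examples
#' mid_age(c("18", "20-29", "80+"))
mid_age <- function(age_group, open_end_mid = 85) {
  ag <- normalize_age_group(age_group)
  known <- standard_age_groups()
  bad <- unique(ag[!ag %in% known])
  if (length(bad) > 0) {
    stop("unknown age group label(s): ", paste(sQuote(bad), collapse = ", "))
  }
  mids <- c(`18` = 18, `19` = 19, `20-29` = 24.5, `30-39` = 34.5,
            `40-49` = 44.5, `50-59` = 54.5, `60-69` = 64.5, `70-79` = 74.5,
            `80+` = open_end_mid)
  unname(mids[ag])
}

#' Birth cohort of an observation
#'
#' The birth cohort is the survey year minus the mid-age of the measured age
#' group; for decade groups this yields half-integer cohorts (e.g. a survey
#' in 2000 of the 20--29 group measures the 1975.5 cohort).
#'
#' @param survey_year Calendar year(s) of measurement.
#' @param age_group Age-group label(s), recycled against `survey_year`.
#' @inheritParams mid_age
#' @return Numeric vector of birth-cohort values (possibly half-integer).
#' @export
#' @examples
#' birth_cohort(2000, "20-29") # 1975.5
#' birth_cohort(1914, "18")    # 1896
birth_cohort <- function(survey_year, age_group, open_end_mid = 85) {
  survey_year - mid_age(age_group, open_end_mid = open_end_mid)
}

#' Restrict a survey table to the analysis set
#'
#' Applies the deterministic inclusion rules: measured (not self-reported)
#' height only, adult age groups (mid-age of at least 18), and birth cohorts
#' within the analysis window. No row is ever excluded for the level of
#' height itself.
#'
#' @param observations Data frame with at least `measured`, `survey_year`,
#'   `age_group` and `study_id` columns (the `observations.csv` schema).
#' @param cohort_min,cohort_max Analysis cohort window, default 1896--1996.
#' @inheritParams mid_age
#' @return A list with `retained` (the filtered tibble, with `mid_age` and
#'   `birth_cohort` columns added) and `excluded` (tibble of
#'   `study_id`, `row`, `reason` for each dropped row).
#' @export
filter_analysis_set <- function(observations, cohort_min = 1896,
                                cohort_max = 1996, open_end_mid = 85) {
  obs <- tibble::as_tibble(observations)
  if (nrow(obs) == 0) {
    empty_log <- tibble::tibble(study_id = character(), row = integer(),
                                reason = character())
    obs$mid_age <- numeric(0)
    obs$birth_cohort <- numeric(0)
    return(list(retained = obs, excluded = empty_log))
  }
  ma <- mid_age(obs$age_group, open_end_mid = open_end_mid)
  bc <- obs$survey_year - ma
  measured <- as.logical(obs$measured)

  reason <- rep(NA_character_, nrow(obs))
  reason[!measured] <- "self-reported"
  reason[is.na(reason) & ma < 18] <- "age group below 18"
  reason[is.na(reason) & bc < cohort_min] <-
    sprintf("cohort before %s", cohort_min)
  reason[is.na(reason) & bc > cohort_max] <-
    sprintf("cohort after %s", cohort_max)

  keep <- is.na(reason)
  retained <- obs[keep, , drop = FALSE]
  retained$mid_age <- ma[keep]
  retained$birth_cohort <- bc[keep]
  excluded <- tibble::tibble(study_id = as.character(obs$study_id[!keep]),
                             row = which(!keep),
                             reason = reason[!keep])
  list(retained = retained, excluded = excluded)
}

#' Flag candidate duplicate data sources
#'
#' Sources from the same country and survey year are grouped as candidate
#' duplicates for human review. Flagging is advisory: nothing is deleted.
#'
#' @param sources Data frame with `study_id`, `country`, `survey_year`
#'   (one row per source; extra columns and repeated rows per source are
#'   tolerated).
#' @return Tibble of flagged groups: `country`, `survey_year`, `group_size`,
#'   `study_ids` (list-column of the member ids). Zero rows when no group
#'   has two or more distinct sources.
#' @export
flag_duplicates <- function(sources) {
  src <- tibble::as_tibble(sources)
  src <- dplyr::distinct(src, .data$study_id, .data$country, .data$survey_year)
  grp <- dplyr::summarise(
    dplyr::group_by(src, .data$country, .data$survey_year),
    group_size = dplyr::n_distinct(.data$study_id),
    study_ids = list(sort(unique(as.character(.data$study_id)))),
    .groups = "drop"
  )
  out <- grp[grp$group_size >= 2, , drop = FALSE]
  dplyr::arrange(out, .data$country, .data$survey_year)
}

#' Classify countries by data availability
#'
#' Strata used to stratify the holdout validation: a (country, sex) series is
#' data-rich with more than 25 observed cohorts of which at least five fall
#' after 1960; data-poor with at most 12 cohorts for women or 8 for men; and
#' of average availability otherwise (13--25 cohorts for women, 9--25 for
#' men, or more than 25 cohorts with fewer than five after 1960).
#'
#' @param cohorts_observed Numeric vector of distinct birth-cohort values
#'   with data for one (country, sex).
#' @param sex `"male"` or `"female"`.
#' @return One of `"data_rich"`, `"data_poor"`, `"average"`.
#' @export
classify_data_availability <- function(cohorts_observed, sex) {
  sex <- match.arg(sex, c("male", "female"))
  co <- unique(cohorts_observed)
  n <- length(co)
  if (n < 1) stop("no observed cohorts")
  n_late <- sum(co > 1960)
  if (n > 25) {
    if (n_late >= 5) "data_rich" else "average"
  } else {
    poor_max <- if (sex == "female") 12 else 8
    if (n <= poor_max) "data_poor" else "average"
  }
}

#' Data-availability table for an observation set
#'
#' Convenience wrapper computing [classify_data_availability()] for every
#' (country, sex) in a filtered analysis set.
#'
#' @param observations Filtered observations with `country`, `sex`,
#'   `birth_cohort` columns (output of [filter_analysis_set()]).
#' @return Tibble with `country`, `sex`, `n_cohorts`, `stratum`.
#' @export
availability_table <- function(observations) {
  obs <- tibble::as_tibble(observations)
  dplyr::summarise(
    dplyr::group_by(obs, .data$country, .data$sex),
    n_cohorts = dplyr::n_distinct(.data$birth_cohort),
    stratum = classify_data_availability(unique(.data$birth_cohort),
                                         .data$sex[1]),
    .groups = "drop"
  )
}

# ---- I/O ---------------------------------------------------------------

observation_cols <- function() {
  c("study_id", "country", "sex", "coverage", "scope", "survey_year",
    "age_group", "mean_cm", "se_cm", "n", "measured")
}

#' Read an observations table
#'
#' Reads the `observations.csv` schema: one row per study x sex x age group,
#' with columns study_id, country, sex, coverage, scope, survey_year,
#' age_group, mean_cm, se_cm, n, measured.
#'
#' @param path Path to a CSV file.
#' @param validate Check field invariants (positive SEs, plausible means,
#'   known age groups and factor levels). Default TRUE.
#' @return Tibble of observations.
#' @export
read_observations <- function(path, validate = TRUE) {
  obs <- readr::read_csv(path, col_types = readr::cols(
    study_id = readr::col_character(),
    country = readr::col_character(),
    sex = readr::col_character(),
    coverage = readr::col_character(),
    scope = readr::col_character(),
    survey_year = readr::col_double(),
    age_group = readr::col_character(),
    mean_cm = readr::col_double(),
    se_cm = readr::col_double(),
    n = readr::col_double(),
    measured = readr::col_logical()
  ))
  missing <- setdiff(observation_cols(), names(obs))
  if (length(missing) > 0) {
    stop("observations file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (validate) validate_observations(obs)
  obs
}

#' Validate observation invariants
#'
#' @param observations Observation tibble.
#' @return The input, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_observations <- function(observations) {
  obs <- observations
  stopifnot(is.data.frame(obs))
  if (!all(obs$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (!all(obs$coverage %in% c("national", "subnational", "community"))) {
    stop("coverage must be national, subnational or community")
  }
  if (!all(obs$scope %in% c("urban", "rural", "mixed"))) {
    stop("scope must be urban, rural or mixed")
  }
  if (any(obs$se_cm <= 0)) stop("se_cm must be > 0")
  if (any(obs$n < 1)) stop("n must be >= 1")
  if (any(obs$mean_cm <= 100 | obs$mean_cm >= 220)) {
    stop("mean_cm must lie in (100, 220)")
  }
  mid_age(obs$age_group) # errors on unknown labels
  invisible(observations)
}

#' Write an observations table
#'
#' @param observations Observation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  readr::write_csv(observations[, observation_cols()], path)
  invisible(path)
}

#' Write an exclusion log
#'
#' @param excluded The `excluded` component of [filter_analysis_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(excluded, path) {
  readr::write_csv(excluded, path)
  invisible(path)
}
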