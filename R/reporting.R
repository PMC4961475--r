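#' Century change in height with credible interval
#'
#' Change in population mean height at age 18 between two cohorts, computed
#' on the posterior sample of the difference draw by draw (not by
#' differencing summary intervals, which would overstate uncertainty).
#'
#' @param fit A `heightfit`.
#' @param countries Countries to report; default all.
#' @param from,to Grid cohorts; default the grid ends (1896 and 1996 for
#'   the default grid).
#' @return Tibble `country`, `sex`, `from`, `to`, `change_cm`, `lo_cm`,
#'   `hi_cm`.
#' @export
century_change <- function(fit, countries = NULL, from = NULL, to = NULL) {
  if (is.null(countries)) countries <- fit$hierarchy$countries
  grid <- fit$grid
  if (is.null(from)) from <- grid[1]
  if (is.null(to)) to <- grid[length(grid)]
  ki <- match(c(from, to), grid)
  if (anyNA(ki)) stop("cohorts must lie on the model grid")
  ci <- match(countries, fit$hierarchy$countries)
  if (anyNA(ci)) stop("unknown country")
  draws <- pooled_draws(fit)$curves
  rows <- lapply(seq_along(ci), function(a) {
    d <- draws[ci[a], ki[2], ] - draws[ci[a], ki[1], ]
    tibble::tibble(country = countries[a], sex = fit$sex, from = from,
                   to = to, change_cm = mean(d),
                   lo_cm = qtl(d, 0.025), hi_cm = qtl(d, 0.975))
  })
  dplyr::bind_rows(rows)
}

#' Rank countries by height at a cohort
#'
#' Rank 1 is the tallest posterior mean; ties are broken deterministically
#' by country code (alphabetical).
#'
#' @param table An estimate table ([summarize_fit()]).
#' @param cohort Birth cohort to rank at; every country must have a row.
#' @param sex Sex to rank (required if the table mixes sexes).
#' @return Tibble `rank`, `country`, `mean_cm`, ordered tallest first.
#' @export
rank_countries <- function(table, cohort, sex = NULL) {
  tab <- tibble::as_tibble(table)
  if (!is.null(sex)) tab <- tab[tab$sex == sex, ]
  if (length(unique(tab$sex)) > 1) stop("rank one sex at a time")
  tab <- tab[tab$birth_cohort == cohort, ]
  all_countries <- unique(table$country)
  if (!setequal(tab$country, all_countries) ||
      nrow(tab) != length(all_countries)) {
    stop("every country needs exactly one row at the requested cohort")
  }
  ord <- order(-tab$mean_cm, tab$country)
  tibble::tibble(rank = seq_along(ord), country = tab$country[ord],
                 mean_cm = tab$mean_cm[ord])
}

#' Male-female height gap at a cohort
#'
#' Per-country gap (men minus women) plus cross-country summaries: the mean
#' gap and the Pearson correlation of men's and women's posterior-mean
#' heights across countries.
#'
#' @param men_table,women_table Estimate tables for each sex over the same
#'   countries.
#' @param cohort Birth cohort.
#' @return List with `by_country` (tibble `country`, `men_cm`, `women_cm`,
#'   `gap_cm`), `mean_gap_cm`, and `correlation` (NA with a single
#'   country, where it is undefined).
#' @export
sex_gap <- function(men_table, women_table, cohort) {
  m <- men_table[men_table$birth_cohort == cohort, ]
  w <- women_table[women_table$birth_cohort == cohort, ]
  if (!setequal(m$country, w$country)) {
    stop("men's and women's tables must cover the same countries")
  }
  m <- m[order(m$country), ]; w <- w[order(w$country), ]
  by_country <- tibble::tibble(country = m$country, men_cm = m$mean_cm,
                               women_cm = w$mean_cm,
                               gap_cm = m$mean_cm - w$mean_cm)
  correlation <- if (nrow(by_country) < 2) NA_real_ else
    stats::cor(by_country$men_cm, by_country$women_cm)
  list(by_country = by_country, mean_gap_cm = mean(by_country$gap_cm),
       correlation = correlation)
}

#' Plot estimated height trends with data overlay
#'
#' Trend lines with shaded 95% credible bands, with the study-summary data
#' points overlaid (data points sit at height measured at the actual age;
#' the line is height at age 18).
#'
#' @param table An estimate table.
#' @param observations Optional observation tibble to overlay (filtered,
#'   with `birth_cohort`).
#' @param countries Countries to show; default the first 6 in the table.
#' @return A ggplot object.
#' @export
plot_trends <- function(table, observations = NULL, countries = NULL) {
  if (is.null(countries)) countries <- utils::head(unique(table$country), 6)
  tab <- table[table$country %in% countries, ]
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$birth_cohort)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo_cm,
                                      ymax = .data$hi_cm),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_cm),
                       color = "steelblue") +
    ggplot2::facet_wrap(~country) +
    ggplot2::labs(x = "birth cohort",
                  y = "mean height at age 18 (cm)")
  if (!is.null(observations)) {
    obs <- observations[observations$country %in% countries &
                          observations$sex %in% unique(tab$sex), ]
    if (nrow(obs) > 0) {
      p <- p + ggplot2::geom_point(
        data = obs,
        ggplot2::aes(x = .data$birth_cohort, y = .data$mean_cm),
        size = 0.5, alpha = 0.4)
    }
  }
  p
}
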