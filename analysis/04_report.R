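#!/usr/bin/env Rscript
# Step 4 — headline summaries from the fitted model: century change with
# credible intervals, country rankings for the 1896 and 1996 cohorts,
# male-female gaps, and trend figures for a sample of countries.
#
# Change summaries need posterior draws (the interval of a difference is
# computed draw by draw), so the models are refitted here with the same
# seeds as 02_fit.R; rankings and gaps work from estimates.csv.

suppressPackageStartupMessages(library(heighttrends))

obs <- read_observations("results/world/observations.csv")
analysis <- filter_analysis_set(obs)
hierarchy <- make_hierarchy(60, 12, 4, seed = 20260919)
config <- model_config(grid_step = 2)

est <- readr::read_csv("results/estimates.csv", show_col_types = FALSE)
changes <- list()
for (sex in c("male", "female")) {
  mc <- mcmc_config(n_chains = 2, n_burnin = 500, n_samples = 1500,
                    seed = 11 + match(sex, c("male", "female")))
  f <- fit(analysis$retained[analysis$retained$sex == sex, ],
           hierarchy, config, mc)
  changes[[sex]] <- century_change(f)

  p <- plot_trends(est[est$sex == sex, ],
                   analysis$retained[analysis$retained$sex == sex, ],
                   countries = sprintf("C%03d", 1:6))
  ggplot2::ggsave(sprintf("results/trends_%s.png", sex), p,
                  width = 8, height = 5, dpi = 150)
}
change <- dplyr::bind_rows(changes)
readr::write_csv(change, "results/century_change.csv")

ranks <- dplyr::bind_rows(lapply(c("male", "female"), function(sx) {
  dplyr::bind_rows(lapply(c(1896, 1996), function(coh) {
    rk <- rank_countries(est[est$sex == sx, ], coh)
    rk$sex <- sx; rk$birth_cohort <- coh; rk
  }))
}))
readr::write_csv(ranks, "results/rankings.csv")

gaps <- dplyr::bind_rows(lapply(c(1896, 1996), function(coh) {
  g <- sex_gap(est[est$sex == "male", ], est[est$sex == "female", ], coh)
  tibble::tibble(birth_cohort = coh, mean_gap_cm = g$mean_gap_cm,
                 correlation = g$correlation)
}))
readr::write_csv(gaps, "results/sex_gap.csv")

big <- change[order(-change$change_cm), ]
message("largest century gains:")
print(utils::head(big, 5))
message(sprintf("sex gap: %.1f cm (1896) -> %.1f cm (1996); cross-country correlation %.2f / %.2f",
                gaps$mean_gap_cm[1], gaps$mean_gap_cm[2],
                gaps$correlation[1], gaps$correlation[2]))
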