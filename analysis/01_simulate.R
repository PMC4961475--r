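#!/usr/bin/env Rscript
# Step 1 — build the synthetic study database.
#
# Generates the world this analysis runs on: 60 countries in 12 regions and
# 4 super-regions, sex-specific ground-truth height surfaces for cohorts
# 1896-1996, and a survey database with the composition of real pooled
# anthropometry databases (54% national / 14% subnational / 32% community
# sources, skewed study counts per country, standard age groups). Applies
# the deterministic preparation rules: analysis-set filter, duplicate
# flagging, and data-availability classification.

suppressPackageStartupMessages(library(heighttrends))
dir.create("results", showWarnings = FALSE)

seed <- 20260919
world <- simulate_world(n_countries = 60, n_regions = 12,
                        n_super_regions = 4, seed = seed)
write_world(world, "results/world")

analysis <- filter_analysis_set(world$observations)
write_exclusion_log(analysis$excluded, "results/exclusion_log.csv")

dup <- flag_duplicates(dplyr::distinct(world$observations, study_id,
                                       country, survey_year))
availability <- availability_table(analysis$retained)
readr::write_csv(availability, "results/availability.csv")

message(sprintf("database: %d rows from %d studies in %d countries",
                nrow(world$observations),
                dplyr::n_distinct(world$observations$study_id),
                dplyr::n_distinct(world$observations$country)))
message(sprintf("analysis set: %d rows retained, %d excluded (%s)",
                nrow(analysis$retained), nrow(analysis$excluded),
                paste(unique(analysis$excluded$reason), collapse = "; ")))
message(sprintf("duplicate candidates flagged for review: %d groups",
                nrow(dup)))
print(table(availability$stratum, availability$sex))
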