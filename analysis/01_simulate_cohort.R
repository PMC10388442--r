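#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Two cohorts mirror the two-part design: a large recall cohort for the
# FFQ coverage evaluation (553 enrolled, of whom 121 are marked as having
# incomplete recall data) and a small screening cohort (48 athletes,
# 29 men / 19 women) with blood panels and baseline/follow-up FFQs.
# Bulky intermediates go to scratch/data/; later stages read from there.

suppressPackageStartupMessages(library(dietscreen))
dir.create("scratch/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20260922

## -- part 1 cohort: multi-day 24-h recalls ---------------------------------
n_enrolled <- 553
n_incomplete <- 121
n_complete <- n_enrolled - n_incomplete

sim <- simulate_recalls(n_complete, seed = seed)

# the recall generator models honest reporting; emulate energy
# under-reporting by scaling 13 athletes' reported amounts down so the
# plausibility screen has true positives to find
set.seed(seed)
under_reporters <- sample(unique(sim$records$person_id), 13)
scale_down <- sim$records$person_id %in% under_reporters
sim$records$amount_g[scale_down] <- sim$records$amount_g[scale_down] * 0.40

write_recalls(sim$records, sim$fct,
              "scratch/data/recalls.csv", "scratch/data/fct.csv")
readr::write_csv(sim$mapping, "scratch/data/ffq_mapping.csv")

set.seed(seed + 1)
profiles <- tibble::tibble(
  person_id = sort(unique(sim$records$person_id)),
  sex = sample(c("male", "female"), n_complete, replace = TRUE,
               prob = c(0.59, 0.41)),
  age_y = sample(18:45, n_complete, replace = TRUE),
  weight_kg = round(stats::rnorm(n_complete, 72, 9), 1)
)
readr::write_csv(profiles, "scratch/data/profiles.csv")

## -- part 2 cohort: FFQ responses, blood panels, satisfaction --------------
ffq_baseline <- simulate_ffq(48, adherence = 0.68, seed = seed + 2)
ffq_followup <- simulate_ffq(29, adherence = 0.70, seed = seed + 3)
readr::write_csv(ffq_baseline, "scratch/data/ffq_baseline.csv")
readr::write_csv(ffq_followup, "scratch/data/ffq_followup.csv")

panels <- simulate_panels(
  29, 19,
  prevalence = list(
    vitd_nmol_l = list(below = 0.25),          # winter vitamin D deficiency
    ferritin_ug_l = list(below = 0.15),        # depleted iron stores (women)
    vitb6_nmol_l = list(above = 0.06),         # over-supplementation pattern
    vitb12_pmol_l = list(above = 0.08)
  ),
  seed = seed + 4
)
readr::write_csv(panels, "scratch/data/panels.csv")

set.seed(seed + 5)
diet_types <- tibble::tibble(
  person_id = ffq_baseline$person_id[!duplicated(ffq_baseline$person_id)],
  diet_type = sample(c("omnivore", "flexitarian", "vegetarian"), 48,
                     replace = TRUE, prob = c(0.6, 0.2, 0.2))
)
readr::write_csv(diet_types, "scratch/data/diet_types.csv")

cat(sprintf(
  "simulated %d recall persons (%d recall rows), 48 screening athletes\n",
  n_complete, nrow(sim$records)
))
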