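#!/usr/bin/env Rscript
# Stage 2: energy-intake plausibility screen and FFQ nutrient-coverage
# evaluation on the recall cohort from stage 1.
#
# Reported energy intake is screened with the Goldberg cutoff (EI/BMR <
# 0.87 excluded, Schofield BMR); MOM1/MOM2 sum scores over FFQ-mapped
# foods then decide per nutrient whether the questionnaire sufficiently
# covers intake (both sums >= 80 %), and candidate foods (MOM >= 1 %,
# unmapped) are proposed for failing nutrients.

suppressPackageStartupMessages(library(dietscreen))
dir.create("results", showWarnings = FALSE)

loaded <- load_recalls("scratch/data/recalls.csv", "scratch/data/fct.csv")
mapping <- load_ffq_mapping("scratch/data/ffq_mapping.csv")
profiles <- readr::read_csv("scratch/data/profiles.csv", show_col_types = FALSE)

intake <- compute_person_intake(loaded$records, loaded$fct)
gf <- goldberg_filter(intake, profiles, cutoff = 0.87)
cat(sprintf("Goldberg screen: %d of %d persons excluded (EI/BMR < 0.87)\n",
            sum(gf$results$excluded), nrow(gf$results)))
readr::write_csv(gf$results, "results/plausibility.csv")

nutrients <- setdiff(dietscreen_nutrients(), "energy_kj")
cov <- coverage_report(gf$kept, mapping, nutrients = nutrients)
report <- dplyr::mutate(cov$report, dplyr::across(dplyr::where(is.numeric),
                                                  ~ round(.x, 1)))
readr::write_csv(report, "results/coverage_report.csv")
readr::write_csv(dplyr::mutate(cov$candidates,
                               dplyr::across(dplyr::where(is.numeric),
                                             ~ round(.x, 1))),
                 "results/coverage_candidates.csv")

cat("coverage sum scores (MOM1/MOM2, % of level and variance captured):\n")
print(as.data.frame(report), row.names = FALSE)
insuff <- report$nutrient[!report$sufficient]
cat(sprintf("insufficiently covered: %s\n",
            if (length(insuff)) paste(insuff, collapse = ", ") else "none"))
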