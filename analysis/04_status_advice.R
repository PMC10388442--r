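#!/usr/bin/env Rscript
# Stage 4: classify blood panels against reference ranges, tabulate
# below/above-range prevalence, and generate the personalised advice
# bundles from the combination of blood status and diet scores.

suppressPackageStartupMessages(library(dietscreen))
dir.create("results", showWarnings = FALSE)

panels <- readr::read_csv("scratch/data/panels.csv", show_col_types = FALSE)
dhd <- readr::read_csv("results/dhd_baseline.csv", show_col_types = FALSE)
nutrients <- readr::read_csv("results/nutrient_scores_baseline.csv",
                             show_col_types = FALSE)
diet_types <- readr::read_csv("scratch/data/diet_types.csv",
                              show_col_types = FALSE)

cls <- classify_panel(panels)
prev <- prevalence(cls)
readr::write_csv(prev, "results/status_prevalence.csv")
flagged <- prev[prev$sex != "all" & (prev$n_below > 0 | prev$n_above > 0), ]
cat("analytes with out-of-range values (by sex):\n")
print(as.data.frame(flagged[, c("analyte", "sex", "n", "n_below", "n_above")]),
      row.names = FALSE)

# advice needs diet scores and blood status keyed to the same person ids
cls$person_id <- dhd$person_id[match(cls$person_id, panels$person_id)]
diet_types$person_id <- dhd$person_id[seq_len(nrow(diet_types))]

bundles <- advise_cohort(dhd, nutrients, cls, diet_types)
items <- purrr::map_dfr(bundles, function(b) {
  dplyr::mutate(b$items, person_id = b$person_id,
                further_diagnostics = b$further_diagnostics)
})
readr::write_csv(items, "results/advice_items.csv")
jsonlite::write_json(
  lapply(bundles, function(b) list(
    person_id = b$person_id, diet_type = b$diet_type,
    further_diagnostics = b$further_diagnostics,
    items = b$items
  )),
  "results/advice_bundles.json", auto_unbox = TRUE, digits = NA
)

cat(sprintf("advice: %d items across %d athletes; diagnostics flagged for %d\n",
            nrow(items), length(bundles),
            sum(vapply(bundles, `[[`, logical(1), "further_diagnostics"))))
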