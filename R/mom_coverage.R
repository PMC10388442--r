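#' Per-food contribution to total nutrient intake (MOM1)
#'
#' The first moment statistic: the percentage each food contributes to
#' the cohort-total intake of a nutrient, computed on person-level mean
#' daily contributions (after day-averaging).  For food f,
#' `mom1_f = 100 * sum_i x_if / sum_i T_i`, where `x_if` is person i's
#' mean daily contribution of f and `T_i` their total.  Values sum to
#' 100 over foods.
#'
#' @param intake A `person_intake` object from [compute_person_intake()].
#' @param nutrient One nutrient name from [dietscreen_nutrients()].
#' @return Named numeric vector: percentage per food code.
#' @export
mom1 <- function(intake, nutrient) {
  contrib <- person_food_matrix(intake, nutrient)
  total <- sum(contrib)
  if (total <= 0) {
    ds_abort(
      sprintf("total intake of %s is zero; MOM1 undefined", nutrient),
      "dietscreen_undefined_statistic_error"
    )
  }
  100 * colSums(contrib) / total
}

#' Per-food contribution to between-person intake variance (MOM2)
#'
#' The second moment statistic: the percentage each food contributes to
#' the between-person variance of a nutrient's intake.  Using the exact
#' additive variance decomposition
#' `Var(T) = sum_f Cov(x_f, T)` with `T_i = sum_f x_if`, the share of
#' food f is `mom2_f = 100 * Cov(x_f, T) / Var(T)` (sample covariance and
#' variance over persons).  Shares sum to 100; a food negatively
#' covarying with the total carries a negative share.
#'
#' @inheritParams mom1
#' @return Named numeric vector: signed percentage per food code.
#' @export
mom2 <- function(intake, nutrient) {
  contrib <- person_food_matrix(intake, nutrient)
  if (nrow(contrib) < 2) {
    ds_abort("MOM2 needs at least two persons",
             "dietscreen_degenerate_variance_error")
  }
  total <- rowSums(contrib)
  v <- stats::var(total)
  if (!is.finite(v) || v <= 0) {
    ds_abort(
      sprintf("between-person variance of %s intake is zero; MOM2 undefined",
              nutrient),
      "dietscreen_degenerate_variance_error"
    )
  }
  shares <- apply(contrib, 2, function(x) stats::cov(x, total)) / v
  100 * shares
}

# internal: complete person x food matrix of mean daily contributions for
# one nutrient (zeros for foods a person never reported)
person_food_matrix <- function(intake, nutrient) {
  stopifnot(inherits(intake, "person_intake"))
  contrib <- intake$contributions[intake$contributions$nutrient == nutrient, ]
  if (nrow(contrib) == 0) {
    ds_abort(sprintf("nutrient '%s' not present in intake data", nutrient),
             "dietscreen_validation_error")
  }
  wide <- tidyr::pivot_wider(
    contrib[, c("person_id", "food_code", "mean_daily")],
    names_from = "food_code", values_from = "mean_daily", values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$person_id
  m[, order(colnames(m)), drop = FALSE]
}

#' MOM1/MOM2 table over nutrients
#'
#' @inheritParams mom1
#' @param nutrients Nutrient names (default: all in the intake data).
#' @return Tibble `nutrient`, `food_code`, `mom1`, `mom2`.
#' @export
mom_table <- function(intake, nutrients = unique(intake$totals$nutrient)) {
  purrr::map_dfr(nutrients, function(nut) {
    m1 <- mom1(intake, nut)
    m2 <- mom2(intake, nut)
    tibble::tibble(
      nutrient = nut,
      food_code = names(m1),
      mom1 = unname(m1),
      mom2 = unname(m2[names(m1)])
    )
  })
}

#' Read a food-to-FFQ-item mapping table
#'
#' @param path CSV with columns `food_code`, `ffq_item_id` (empty =
#'   unmapped), `label`.
#' @return Tibble with `ffq_item_id` `NA` where the food has no FFQ item.
#' @export
load_ffq_mapping <- function(path) {
  mapping <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  check_columns(mapping, c("food_code", "ffq_item_id"), "mapping file")
  mapping$ffq_item_id[mapping$ffq_item_id %in% c("", "UNMAPPED")] <- NA
  tibble::as_tibble(mapping)
}

# internal: mapped food codes; errors if foods in the MOM table lack a
# mapping row entirely
mapped_foods <- function(mom, mapping) {
  gap <- setdiff(unique(mom$food_code), mapping$food_code)
  if (length(gap) > 0) {
    ds_abort(
      sprintf("food code(s) missing from the FFQ mapping: %s",
              paste(sort(gap), collapse = ", ")),
      "dietscreen_mapping_gap_error"
    )
  }
  mapping$food_code[!is.na(mapping$ffq_item_id)]
}

#' MOM1/MOM2 sum scores over FFQ-mapped foods
#'
#' Sums per-food MOM values over the foods that could be assigned to an
#' FFQ item (unmapped foods are left out); the sum score is the share of
#' the level (MOM1) and between-person variance (MOM2) of each nutrient
#' that the FFQ captures.
#'
#' @param mom Tibble from [mom_table()].
#' @param mapping Tibble from [load_ffq_mapping()].
#' @return Tibble `nutrient`, `mom1_sum`, `mom2_sum` (percent).
#' @export
sum_scores <- function(mom, mapping) {
  mapped <- mapped_foods(mom, mapping)
  mom |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::summarise(
      mom1_sum = sum(.data$mom1[.data$food_code %in% mapped]),
      mom2_sum = sum(.data$mom2[.data$food_code %in% mapped]),
      .groups = "drop"
    )
}

#' Sufficient-coverage decision
#'
#' A nutrient counts as sufficiently covered when both the MOM1 and the
#' MOM2 sum score reach the threshold (inclusive; default 80 %).
#'
#' @param sums Tibble from [sum_scores()].
#' @param threshold Percent threshold, inclusive.
#' @return `sums` with a logical `sufficient` column.
#' @export
coverage_decision <- function(sums, threshold = 80) {
  dplyr::mutate(
    sums,
    sufficient = .data$mom1_sum >= threshold & .data$mom2_sum >= threshold
  )
}

#' Candidate foods for addition to the FFQ
#'
#' For the given nutrients, returns the unmapped foods whose MOM1 or
#' MOM2 value reaches `min_pct` (the and/or rule), ordered by
#' `max(mom1, mom2)` descending with lexicographic food-code tie-break.
#' Intended to be run only for nutrients that fail the coverage decision.
#'
#' @inheritParams sum_scores
#' @param min_pct Minimum percent on either moment (default 1).
#' @param nutrients Nutrients to evaluate (default: all in `mom`).
#' @return Tibble `nutrient`, `food_code`, `mom1`, `mom2`.
#' @export
candidate_additions <- function(mom, mapping, min_pct = 1,
                                nutrients = unique(mom$nutrient)) {
  mapped <- mapped_foods(mom, mapping)
  mom |>
    dplyr::filter(
      .data$nutrient %in% nutrients,
      !(.data$food_code %in% mapped),
      .data$mom1 >= min_pct | .data$mom2 >= min_pct
    ) |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::arrange(dplyr::desc(pmax(.data$mom1, .data$mom2)),
                   .data$food_code, .by_group = TRUE) |>
    dplyr::ungroup()
}

#' Recompute sum scores with candidate foods treated as mapped
#'
#' @inheritParams sum_scores
#' @param additions Food codes currently unmapped; treating them as
#'   mapped can only raise each nutrient's sums (MOM1 is nonnegative and
#'   MOM2 additions are the candidates' own shares).
#' @return Tibble `nutrient`, `mom1_sum`, `mom2_sum` after addition.
#' @export
recompute_with_additions <- function(mom, mapping, additions) {
  already <- intersect(additions, mapped_foods(mom, mapping))
  if (length(already) > 0) {
    ds_abort(
      sprintf("food(s) already mapped to an FFQ item: %s",
              paste(sort(already), collapse = ", ")),
      "dietscreen_validation_error"
    )
  }
  augmented <- mapping
  augmented$ffq_item_id[augmented$food_code %in% additions] <- "ADDED"
  sum_scores(mom, augmented)
}

#' Full FFQ nutrient-coverage report
#'
#' Runs the complete coverage evaluation: MOM1/MOM2 per food, sum scores
#' over FFQ-mapped foods, the sufficiency decision, and — for nutrients
#' failing it — the candidate-addition search and the recomputed sums
#' with all candidates included.
#'
#' @inheritParams mom1
#' @inheritParams candidate_additions
#' @param threshold Sufficiency threshold, percent (inclusive).
#' @return List with `mom` (the MOM table), `report` (per-nutrient sums,
#'   decision, and post-addition sums; `NA` where no search was run) and
#'   `candidates` (per-nutrient candidate foods).
#' @export
coverage_report <- function(intake, mapping,
                            nutrients = unique(intake$totals$nutrient),
                            threshold = 80, min_pct = 1) {
  mom <- mom_table(intake, nutrients)
  report <- coverage_decision(sum_scores(mom, mapping), threshold)
  failing <- report$nutrient[!report$sufficient]
  candidates <- candidate_additions(mom, mapping, min_pct, failing)
  report$mom1_sum_with_candidates <- NA_real_
  report$mom2_sum_with_candidates <- NA_real_
  for (nut in failing) {
    adds <- candidates$food_code[candidates$nutrient == nut]
    new_sums <- recompute_with_additions(
      mom[mom$nutrient == nut, ], mapping, unique(adds)
    )
    i <- report$nutrient == nut
    report$mom1_sum_with_candidates[i] <- new_sums$mom1_sum
    report$mom2_sum_with_candidates[i] <- new_sums$mom2_sum
  }
  list(mom = mom, report = report, candidates = candidates)
}
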