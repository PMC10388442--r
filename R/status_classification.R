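#' Load blood reference ranges
#'
#' Sex-specific reference intervals per analyte.  The packaged file holds
#' example values mirroring typical Dutch hospital ranges; real
#' applications must supply the ranges of the laboratory that produced
#' the panel.
#'
#' @param path YAML file: `analyte -> sex (or "any") -> {low, high}`.
#' @return Tibble `analyte`, `sex`, `low`, `high`.
#' @export
load_reference_ranges <- function(path = ds_extdata("reference_ranges_example.yaml")) {
  raw <- yaml::read_yaml(path)
  ranges <- purrr::imap_dfr(raw$ranges, function(by_sex, analyte) {
    purrr::imap_dfr(by_sex, function(r, sex) {
      tibble::tibble(analyte = analyte, sex = sex,
                     low = r$low, high = r$high)
    })
  })
  if (any(ranges$low >= ranges$high)) {
    ds_abort("reference range with low >= high", "dietscreen_config_error")
  }
  ranges
}

#' Analytes measured in the blood panel
#' @return Character vector of panel column names.
#' @export
panel_analytes <- function() {
  c("vitb6_nmol_l", "folate_nmol_l", "vitb12_pmol_l",
    "vitd_nmol_l", "hb_mmol_l", "ferritin_ug_l")
}

#' Classify blood panels against reference ranges
#'
#' Each present analyte is classified `below` (value < low), `above`
#' (value > high) or `within` (bounds inclusive); absent values are
#' `missing`.  Ranges are matched by the person's sex, falling back to a
#' shared `"any"` entry for analytes without sex differences.
#'
#' @param panels Tibble `person_id`, `sex`, plus analyte columns
#'   ([panel_analytes()]); `NA` = not measured.
#' @param ranges Tibble from [load_reference_ranges()].
#' @return Tibble `person_id`, `sex`, `analyte`, `value`, `status`
#'   (factor below/within/above/missing).
#' @export
classify_panel <- function(panels, ranges = load_reference_ranges()) {
  analytes <- intersect(panel_analytes(), names(panels))
  check_columns(panels, c("person_id", "sex"), "blood panel")
  long <- tidyr::pivot_longer(panels[, c("person_id", "sex", analytes)],
                              dplyr::all_of(analytes),
                              names_to = "analyte", values_to = "value")
  if (any(long$value <= 0, na.rm = TRUE)) {
    ds_abort("blood concentrations must be strictly positive",
             "dietscreen_validation_error")
  }
  sexed <- dplyr::left_join(long, ranges, by = c("analyte", "sex"))
  shared <- dplyr::left_join(long, ranges[ranges$sex == "any", c("analyte", "low", "high")],
                             by = "analyte")
  sexed$low <- dplyr::coalesce(sexed$low, shared$low)
  sexed$high <- dplyr::coalesce(sexed$high, shared$high)
  uncovered <- sexed[!is.na(sexed$value) & is.na(sexed$low), ]
  if (nrow(uncovered) > 0) {
    ds_abort(
      sprintf("no reference range for analyte(s): %s",
              paste(sort(unique(paste(uncovered$analyte, uncovered$sex, sep = "/"))),
                    collapse = ", ")),
      "dietscreen_config_error"
    )
  }
  sexed |>
    dplyr::mutate(
      status = factor(
        dplyr::case_when(
          is.na(.data$value) ~ "missing",
          .data$value < .data$low ~ "below",
          .data$value > .data$high ~ "above",
          TRUE ~ "within"
        ),
        levels = c("below", "within", "above", "missing")
      )
    ) |>
    dplyr::select("person_id", "sex", "analyte", "value", "status")
}

#' Prevalence of below/above-range blood values
#'
#' Counts and percentages of classifications per analyte, overall and by
#' sex.  Percentages use the non-missing denominator and integer counts
#' are preserved alongside.
#'
#' @param classifications Tibble from [classify_panel()].
#' @return Tibble: `analyte`, `sex` (`"all"` plus each sex), `n`,
#'   `n_below`, `n_within`, `n_above`, `n_missing`, `pct_below`,
#'   `pct_above` (percent of non-missing).
#' @export
prevalence <- function(classifications) {
  if (nrow(classifications) == 0) {
    ds_abort("no classifications to summarise", "dietscreen_empty_report_error")
  }
  both <- dplyr::bind_rows(
    classifications,
    dplyr::mutate(classifications, sex = "all")
  )
  both |>
    dplyr::group_by(.data$analyte, .data$sex) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_below = sum(.data$status == "below"),
      n_within = sum(.data$status == "within"),
      n_above = sum(.data$status == "above"),
      n_missing = sum(.data$status == "missing"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_below = 100 * .data$n_below / pmax(.data$n - .data$n_missing, 1),
      pct_above = 100 * .data$n_above / pmax(.data$n - .data$n_missing, 1)
    )
}
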