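#' Load Schofield BMR coefficients
#'
#' Basal metabolic rate is estimated from the weight-only Schofield
#' regression equations, BMR (MJ/day) = slope x weight (kg) + intercept,
#' with coefficients per sex and age band.  The coefficients are
#' configuration data; the packaged default reproduces the published
#' weight-only equations by sex and age band.
#'
#' @param path YAML file; each entry has `sex`, `age_min`, `age_max`,
#'   `slope_mj_per_kg`, `intercept_mj`.  Default: the packaged table.
#' @return Tibble of coefficient bands.
#' @export
load_schofield_coefficients <- function(path = ds_extdata("schofield_bmr.yaml")) {
  raw <- yaml::read_yaml(path)
  coeffs <- purrr::map_dfr(raw$bands, tibble::as_tibble)
  check_columns(coeffs,
                c("sex", "age_min", "age_max", "slope_mj_per_kg", "intercept_mj"),
                "Schofield coefficient file")
  coeffs
}

#' Schofield basal metabolic rate
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @param age Age in years, > 0.
#' @param weight Body weight in kg, > 0.
#' @param coeffs Coefficient tibble from [load_schofield_coefficients()].
#' @return BMR in MJ/day.
#' @export
schofield_bmr <- function(sex, age, weight,
                          coeffs = load_schofield_coefficients()) {
  if (any(weight <= 0) || any(age <= 0)) {
    ds_abort("age and weight must be strictly positive",
             "dietscreen_validation_error")
  }
  n <- max(length(sex), length(age), length(weight))
  sex <- rep_len(sex, n); age <- rep_len(age, n); weight <- rep_len(weight, n)
  vapply(seq_len(n), function(i) {
    band <- coeffs[coeffs$sex == sex[i] &
                     coeffs$age_min <= age[i] & age[i] < coeffs$age_max, ]
    if (nrow(band) == 0) {
      ds_abort(
        sprintf("no Schofield coefficient band for sex %s at age %s",
                sex[i], age[i]),
        "dietscreen_config_error"
      )
    }
    band$slope_mj_per_kg[1] * weight[i] + band$intercept_mj[1]
  }, numeric(1))
}

#' Goldberg plausibility screen for reported energy intake
#'
#' Compares each person's reported energy intake (EI, MJ/day, from the
#' recall-derived mean daily energy) to their Schofield-estimated BMR.
#' Persons whose EI/BMR index falls strictly below the cutoff (default
#' 0.87) are flagged as implausible under-reporters and excluded; an
#' index exactly at the cutoff is kept.  This is the simplified
#' per-individual form of the Goldberg screen (fixed cutoff, no
#' PAL/CV confidence limits).
#'
#' @param intake A `person_intake` object.
#' @param profiles Tibble `person_id`, `sex`, `age_y`, `weight_kg`.
#' @param cutoff EI/BMR exclusion limit (strict less-than).
#' @param coeffs Schofield coefficients, see [schofield_bmr()].
#' @return List with `kept` (a `person_intake` restricted to plausible
#'   reporters) and `results` (tibble `person_id`, `ei_mj`, `bmr_mj`,
#'   `ei_bmr_index`, `excluded`).
#' @export
goldberg_filter <- function(intake, profiles, cutoff = 0.87,
                            coeffs = load_schofield_coefficients()) {
  check_columns(profiles, c("person_id", "sex", "age_y", "weight_kg"),
                "profile table")
  energy <- intake$totals[intake$totals$nutrient == "energy_kj", ]
  unmatched <- setdiff(energy$person_id, profiles$person_id)
  if (length(unmatched) > 0) {
    ds_abort(
      sprintf("no profile for person(s): %s",
              paste(sort(unmatched), collapse = ", ")),
      "dietscreen_matching_error"
    )
  }
  results <- energy |>
    dplyr::transmute(person_id = .data$person_id,
                     ei_mj = .data$intake / 1000) |>
    dplyr::inner_join(profiles, by = "person_id") |>
    dplyr::mutate(
      bmr_mj = schofield_bmr(.data$sex, .data$age_y, .data$weight_kg, coeffs),
      ei_bmr_index = .data$ei_mj / .data$bmr_mj,
      excluded = .data$ei_bmr_index < cutoff
    ) |>
    dplyr::select("person_id", "ei_mj", "bmr_mj", "ei_bmr_index", "excluded")

  keep_ids <- results$person_id[!results$excluded]
  kept <- structure(
    list(
      contributions = intake$contributions[
        intake$contributions$person_id %in% keep_ids, ],
      totals = intake$totals[intake$totals$person_id %in% keep_ids, ],
      n_days = intake$n_days[intake$n_days$person_id %in% keep_ids, ]
    ),
    class = "person_intake"
  )
  list(kept = kept, results = results)
}
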