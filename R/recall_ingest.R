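#' Read 24-h dietary recall records and a food-composition table
#'
#' The recall file holds one row per reported food per person per recall
#' day (grams consumed); the composition table holds nutrient densities
#' per 100 g of each food.  Every food code appearing in the recalls must
#' be resolvable in the composition table: unresolved codes raise an
#' error rather than being dropped, and a missing nutrient density is an
#' error rather than an imputed zero (silent zeros would bias the MOM1
#' level statistics downward undetectably).
#'
#' @param path Recall CSV with columns `person_id`, `recall_day`,
#'   `food_code`, `amount_g`.
#' @param fct_path Composition CSV with columns `food_code`, `name`,
#'   and the nutrient columns of [dietscreen_nutrients()], per 100 g.
#' @param energy_unit Unit of the energy column in the composition file;
#'   `"kcal"` is converted to kJ on input (1 kcal = 4.184 kJ).  Energy is
#'   carried in kJ internally (the Goldberg screen needs MJ/day).
#' @return A list with tibbles `records` and `fct`.
#' @export
load_recalls <- function(path, fct_path, energy_unit = c("kj", "kcal")) {
  energy_unit <- match.arg(energy_unit)
  records <- readr::read_csv(path, show_col_types = FALSE)
  fct <- readr::read_csv(fct_path, show_col_types = FALSE)
  check_columns(records, c("person_id", "recall_day", "food_code", "amount_g"),
                "recall file")
  check_columns(fct, c("food_code", dietscreen_nutrients()),
                "food-composition file")

  bad <- which(!is.finite(records$amount_g) | records$amount_g < 0)
  if (length(bad) > 0) {
    ds_abort(
      sprintf("negative or non-numeric amount_g in recall row(s): %s",
              paste(bad, collapse = ", ")),
      "dietscreen_validation_error"
    )
  }
  unresolved <- setdiff(unique(records$food_code), fct$food_code)
  if (length(unresolved) > 0) {
    ds_abort(
      sprintf("food code(s) absent from the composition table: %s",
              paste(sort(unresolved), collapse = ", ")),
      "dietscreen_unresolved_food_error"
    )
  }
  if (energy_unit == "kcal") {
    fct$energy_kj <- fct$energy_kj * 4.184
  }
  list(
    records = tibble::as_tibble(records),
    fct = tibble::as_tibble(fct)
  )
}

#' Write recall records and a composition table back to CSV
#'
#' Inverse of [load_recalls()]; used to persist simulated datasets in the
#' same dialect the ingestion reads.
#'
#' @param records,fct Tibbles as returned by [load_recalls()].
#' @param path,fct_path Output CSV paths.
#' @export
write_recalls <- function(records, fct, path, fct_path) {
  readr::write_csv(records, path)
  readr::write_csv(fct, fct_path)
  invisible(list(path = path, fct_path = fct_path))
}

#' Per-person mean daily nutrient intake and per-food contributions
#'
#' Converts food amounts to nutrients (amount/100 x density per 100 g),
#' sums within each recall day, and averages over the person's recall
#' days.  Duplicate (person, day, food) rows are summed before the
#' density multiplication, since recalls list foods per eating occasion.
#' The per-food mean daily contributions are retained: they are the
#' substrate of the MOM1/MOM2 coverage statistics, and for every nutrient
#' they sum exactly to the person's total mean daily intake.
#'
#' @param records Recall tibble (`person_id`, `recall_day`, `food_code`,
#'   `amount_g`).
#' @param fct Food-composition tibble (per 100 g).
#' @return An object of class `person_intake`: a list with
#'   \describe{
#'     \item{contributions}{tibble `person_id`, `food_code`, `nutrient`,
#'       `mean_daily` — mean daily contribution of that food to that
#'       nutrient, in the nutrient's unit per day.}
#'     \item{totals}{tibble `person_id`, `nutrient`, `intake` — total mean
#'       daily intake.}
#'     \item{n_days}{tibble `person_id`, `n_days`.}
#'   }
#' @export
compute_person_intake <- function(records, fct) {
  nutrients <- dietscreen_nutrients()
  check_columns(records, c("person_id", "recall_day", "food_code", "amount_g"),
                "recall records")
  check_columns(fct, c("food_code", nutrients), "composition table")
  unresolved <- setdiff(unique(records$food_code), fct$food_code)
  if (length(unresolved) > 0) {
    ds_abort(
      sprintf("food code(s) absent from the composition table: %s",
              paste(sort(unresolved), collapse = ", ")),
      "dietscreen_unresolved_food_error"
    )
  }
  dens <- tidyr::pivot_longer(fct[, c("food_code", nutrients)],
                              dplyr::all_of(nutrients),
                              names_to = "nutrient", values_to = "density")
  if (anyNA(dens$density)) {
    bad <- unique(dens$food_code[is.na(dens$density)])
    ds_abort(
      sprintf("missing nutrient density for food(s): %s",
              paste(sort(bad), collapse = ", ")),
      "dietscreen_validation_error"
    )
  }

  n_days <- records |>
    dplyr::distinct(.data$person_id, .data$recall_day) |>
    dplyr::count(.data$person_id, name = "n_days")

  contributions <- records |>
    dplyr::group_by(.data$person_id, .data$recall_day, .data$food_code) |>
    dplyr::summarise(amount_g = sum(.data$amount_g), .groups = "drop") |>
    dplyr::inner_join(dens, by = "food_code", relationship = "many-to-many") |>
    dplyr::mutate(value = .data$amount_g / 100 * .data$density) |>
    dplyr::group_by(.data$person_id, .data$food_code, .data$nutrient) |>
    dplyr::summarise(day_sum = sum(.data$value), .groups = "drop") |>
    dplyr::inner_join(n_days, by = "person_id") |>
    dplyr::mutate(mean_daily = .data$day_sum / .data$n_days) |>
    dplyr::select("person_id", "food_code", "nutrient", "mean_daily")

  totals <- contributions |>
    dplyr::group_by(.data$person_id, .data$nutrient) |>
    dplyr::summarise(intake = sum(.data$mean_daily), .groups = "drop")

  structure(
    list(contributions = contributions, totals = totals, n_days = n_days),
    class = "person_intake"
  )
}

#' @export
print.person_intake <- function(x, ...) {
  cat(sprintf(
    "<person_intake> %d persons, %d foods, %d nutrients\n",
    nrow(x$n_days),
    length(unique(x$contributions$food_code)),
    length(unique(x$contributions$nutrient))
  ))
  invisible(x)
}
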