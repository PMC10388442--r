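#' Load a short-FFQ definition
#'
#' The FFQ definition lists the questionnaire's food items with their
#' question grouping, the diet-index component each item feeds (with a
#' weight), the soft/solid role of fat items for the fats-and-oils ratio,
#' and per-100 g nutrient densities used for the micronutrient and
#' protein compliance scores.  The packaged default is a synthetic,
#' schema-compatible 40-question / 55-item inventory.
#'
#' @param path YAML file; default the packaged definition.
#' @return List with an `items` tibble (one row per item; density columns
#'   prefixed `density_`).
#' @export
load_ffq_definition <- function(path = ds_extdata("ffq_definition.yaml")) {
  raw <- yaml::read_yaml(path)
  items <- purrr::map_dfr(raw$items, function(it) {
    dens <- it$density
    tibble::tibble(
      item_id = it$id,
      question = it$question,
      label = it$label %||% it$id,
      component = it$component %||% NA_character_,
      weight = it$weight %||% 1,
      ratio_role = it$ratio_role %||% NA_character_,
      !!!stats::setNames(as.list(as.numeric(dens)), paste0("density_", names(dens)))
    )
  })
  if (anyDuplicated(items$item_id)) {
    ds_abort("duplicate item ids in FFQ definition", "dietscreen_config_error")
  }
  list(items = items,
       n_questions = length(unique(items$question)),
       n_items = nrow(items))
}

#' Load DHD2015 component definitions
#'
#' @param path YAML file with exactly 16 component definitions; default
#'   the packaged Dutch-2015-guideline configuration.
#' @return Tibble of component definitions (one row each).
#' @export
load_component_definitions <- function(path = ds_extdata("dhd2015_components.yaml")) {
  raw <- yaml::read_yaml(path)
  defs <- purrr::map_dfr(raw$components, tibble::as_tibble)
  if (nrow(defs) != 16) {
    ds_abort(
      sprintf("the diet-quality index needs exactly 16 component definitions, got %d",
              nrow(defs)),
      "dietscreen_config_error"
    )
  }
  bad <- defs$kind == "moderation" & !(defs$upper > defs$lower)
  if (any(bad, na.rm = TRUE)) {
    ds_abort(
      sprintf("moderation component(s) with upper <= lower: %s",
              paste(defs$id[which(bad)], collapse = ", ")),
      "dietscreen_config_error"
    )
  }
  defs
}

#' Load recommended dietary allowances
#'
#' @param path YAML file; default the packaged adult reference intakes.
#' @return Tibble `nutrient`, `value`, `unit`, `per_kg`.
#' @export
load_rda <- function(path = ds_extdata("rda.yaml")) {
  raw <- yaml::read_yaml(path)
  purrr::imap_dfr(raw$rda, function(x, nm) {
    tibble::tibble(nutrient = nm, value = x$value, unit = x$unit,
                   per_kg = isTRUE(x$per_kg))
  })
}

#' Derive daily component intakes from FFQ responses
#'
#' Converts reported frequencies (times/week) and amounts per occasion
#' into the intake each scoring component needs: g/day for amount-based
#' components (`weight * freq/7 * amount`), occasions/week for
#' frequency-based ones (`weight * freq`), and the soft:solid fat ratio
#' for the ratio component (no solid fat at all counts as full
#' compliance, i.e. an infinite ratio).
#'
#' @param response Tibble `person_id`, `item_id`, `freq_per_week`,
#'   `amount_per_occasion` (g or mL per occasion).
#' @param ffq_def FFQ definition from [load_ffq_definition()].
#' @param components Component definitions from
#'   [load_component_definitions()].
#' @return Tibble `person_id`, `component`, `intake` with every component
#'   present for every person.
#' @export
derive_component_intakes <- function(response, ffq_def,
                                     components = load_component_definitions()) {
  check_columns(response,
                c("person_id", "item_id", "freq_per_week", "amount_per_occasion"),
                "FFQ response")
  items <- ffq_def$items
  unknown <- setdiff(unique(response$item_id), items$item_id)
  if (length(unknown) > 0) {
    ds_abort(
      sprintf("item id(s) not in the FFQ definition: %s",
              paste(sort(unknown), collapse = ", ")),
      "dietscreen_schema_error"
    )
  }
  if (any(response$freq_per_week < 0) || any(response$amount_per_occasion < 0)) {
    ds_abort("frequencies and amounts must be nonnegative",
             "dietscreen_validation_error")
  }

  joined <- dplyr::inner_join(
    response,
    items[, c("item_id", "component", "weight", "ratio_role")],
    by = "item_id"
  ) |>
    dplyr::mutate(
      g_day = .data$weight * .data$freq_per_week / 7 * .data$amount_per_occasion,
      occ_week = .data$weight * .data$freq_per_week
    )

  persons <- unique(response$person_id)
  grid <- tidyr::expand_grid(person_id = persons, component = components$id)
  defs <- components[, c("id", "kind", "basis")]
  names(defs)[1] <- "component"

  plain <- joined |>
    dplyr::filter(!is.na(.data$component)) |>
    dplyr::inner_join(defs, by = "component") |>
    dplyr::filter(.data$kind != "ratio") |>
    dplyr::group_by(.data$person_id, .data$component) |>
    dplyr::summarise(
      intake = sum(ifelse(.data$basis == "frequency", .data$occ_week, .data$g_day)),
      .groups = "drop"
    )

  ratio_ids <- components$id[components$kind == "ratio"]
  ratio <- joined |>
    dplyr::filter(.data$component %in% ratio_ids) |>
    dplyr::group_by(.data$person_id, .data$component) |>
    dplyr::summarise(
      soft = sum(.data$g_day[.data$ratio_role %in% "soft"]),
      solid = sum(.data$g_day[.data$ratio_role %in% "solid"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(intake = ifelse(.data$solid == 0, Inf,
                                  .data$soft / .data$solid)) |>
    dplyr::select("person_id", "component", "intake")

  out <- dplyr::left_join(grid, dplyr::bind_rows(plain, ratio),
                          by = c("person_id", "component"))
  # components a person reported nothing for: zero intake, except the
  # ratio component where "no solid fat" is full compliance
  out$intake[is.na(out$intake) & out$component %in% ratio_ids] <- Inf
  out$intake[is.na(out$intake)] <- 0
  out
}

#' Score one component intake on the 0-10 scale
#'
#' Adequacy components rise linearly to 10 at the guideline threshold;
#' moderation components hold 10 up to the lower bound and fall linearly
#' to 0 at the upper; optimum components score 10 on a plateau and fall
#' to 0 outside it; ratio components rise to 10 at the target ratio;
#' binary components score 10 or 0 around a cutoff.  Results are clipped
#' to \[0, 10\].
#'
#' @param intake Nonnegative intake (vectorised); unit per the
#'   component's basis.
#' @param definition One-row component definition (a row of
#'   [load_component_definitions()], or an equivalent list).
#' @return Score(s) in \[0, 10\].
#' @export
score_component <- function(intake, definition) {
  kind <- definition$kind
  if (any(intake < 0, na.rm = TRUE)) {
    ds_abort("component intake must be nonnegative",
             "dietscreen_validation_error")
  }
  score <- switch(
    kind,
    adequacy = 10 * pmin(intake / definition$threshold, 1),
    moderation = {
      lower <- definition$lower; upper <- definition$upper
      if (!isTRUE(upper > lower)) {
        ds_abort(sprintf("moderation component '%s' has upper <= lower",
                         definition$id %||% "?"),
                 "dietscreen_config_error")
      }
      10 * pmax(0, pmin(1, (upper - intake) / (upper - lower)))
    },
    optimum = {
      lo0 <- definition$low0; lo <- definition$opt_low
      hi <- definition$opt_high; hi0 <- definition$high0
      up <- 10 * pmax(0, pmin(1, (intake - lo0) / (lo - lo0)))
      down <- 10 * pmax(0, pmin(1, (hi0 - intake) / (hi0 - hi)))
      pmin(up, down)
    },
    ratio = ifelse(is.infinite(intake), 10,
                   10 * pmin(intake / definition$threshold, 1)),
    binary = ifelse(intake <= definition$cutoff, 10, 0),
    ds_abort(sprintf("unknown component kind '%s'", kind),
             "dietscreen_config_error")
  )
  pmin(pmax(score, 0), 10)
}

#' Score FFQ responses into the 16-component diet-quality index
#'
#' Derives per-component daily intakes and scores each of the 16
#' components 0-10; the total (0-160) is the exact sum of the component
#' scores.  Micronutrient and protein compliance scores are separate
#' ([score_nutrients()]) and never enter the total.
#'
#' @inheritParams derive_component_intakes
#' @return Tibble: `person_id`, one column per component id (score 0-10),
#'   and `total` (0-160).
#' @export
score_dhd <- function(response, ffq_def = load_ffq_definition(),
                      components = load_component_definitions()) {
  if (nrow(components) != 16) {
    ds_abort("exactly 16 component definitions are required",
             "dietscreen_config_error")
  }
  intakes <- derive_component_intakes(response, ffq_def, components)
  scored <- intakes |>
    dplyr::group_by(.data$component) |>
    dplyr::group_modify(function(df, key) {
      def <- components[components$id == key$component, ]
      df$score <- score_component(df$intake, def)
      df
    }) |>
    dplyr::ungroup()
  wide <- tidyr::pivot_wider(
    scored[, c("person_id", "component", "score")],
    names_from = "component", values_from = "score"
  )
  wide <- wide[, c("person_id", components$id)]
  wide$total <- rowSums(wide[, components$id])
  wide
}

#' Micronutrient and protein compliance scores
#'
#' Estimates daily nutrient intake from the FFQ item densities
#' (`freq/7 * amount * density/100`) and scores compliance with the
#' recommended dietary allowance as `10 * min(intake/RDA, 1)`.  Protein
#' allowances expressed per kg body weight require a body-weight table.
#'
#' @inheritParams derive_component_intakes
#' @param rda RDA tibble from [load_rda()].
#' @param body_weight Optional tibble `person_id`, `weight_kg`; required
#'   when any RDA is per kg.
#' @return Tibble `person_id` plus one score column per nutrient
#'   (`score_<nutrient>`, 0-10).
#' @export
score_nutrients <- function(response, ffq_def = load_ffq_definition(),
                            rda = load_rda(), body_weight = NULL) {
  items <- ffq_def$items
  unknown <- setdiff(unique(response$item_id), items$item_id)
  if (length(unknown) > 0) {
    ds_abort(
      sprintf("item id(s) not in the FFQ definition: %s",
              paste(sort(unknown), collapse = ", ")),
      "dietscreen_schema_error"
    )
  }
  dens_cols <- grep("^density_", names(items), value = TRUE)
  long <- dplyr::inner_join(response, items[, c("item_id", dens_cols)],
                            by = "item_id") |>
    tidyr::pivot_longer(dplyr::all_of(dens_cols),
                        names_to = "nutrient", values_to = "density",
                        names_prefix = "density_") |>
    dplyr::group_by(.data$person_id, .data$nutrient) |>
    dplyr::summarise(
      intake = sum(.data$freq_per_week / 7 * .data$amount_per_occasion *
                     .data$density / 100),
      .groups = "drop"
    )

  scored <- dplyr::inner_join(long, rda, by = "nutrient")
  if (any(scored$per_kg)) {
    if (is.null(body_weight)) {
      ds_abort("body weight is required for per-kg allowances (protein)",
               "dietscreen_input_error")
    }
    check_columns(body_weight, c("person_id", "weight_kg"), "body-weight table")
    scored <- dplyr::left_join(scored, body_weight, by = "person_id")
    if (any(scored$per_kg & is.na(scored$weight_kg))) {
      ds_abort("missing body weight for person(s) with per-kg allowance",
               "dietscreen_input_error")
    }
  } else {
    scored$weight_kg <- NA_real_
  }
  scored |>
    dplyr::mutate(
      rda_abs = ifelse(.data$per_kg, .data$value * .data$weight_kg, .data$value),
      score = 10 * pmin(.data$intake / .data$rda_abs, 1)
    ) |>
    dplyr::select("person_id", "nutrient", "score") |>
    tidyr::pivot_wider(names_from = "nutrient", values_from = "score",
                       names_prefix = "score_")
}
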