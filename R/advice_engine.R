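#' Load advice rules and templates
#'
#' @param path YAML file with component, nutrient and analyte templates
#'   (omnivore and optional vegetarian variants), the analyte-to-nutrient
#'   correspondence used by the cross-interpretation rule, and the
#'   diet-score advice threshold.
#' @return The parsed rule list.
#' @export
load_advice_rules <- function(path = ds_extdata("advice_rules.yaml")) {
  rules <- yaml::read_yaml(path)
  for (part in c("components", "nutrients", "analytes")) {
    if (is.null(rules[[part]])) {
      ds_abort(sprintf("advice rules are missing the '%s' section", part),
               "dietscreen_config_error")
    }
  }
  rules
}

# internal: pick the diet-type variant of a template (vegetarians get the
# vegetarian wording where one exists; flexitarians the omnivore wording)
pick_template <- function(tpl, diet_type, what) {
  if (is.null(tpl)) {
    ds_abort(sprintf("no advice template for %s", what),
             "dietscreen_config_error")
  }
  if (identical(diet_type, "vegetarian") && !is.null(tpl$vegetarian)) {
    tpl$vegetarian
  } else if (!is.null(tpl$omnivore)) {
    tpl$omnivore
  } else {
    ds_abort(sprintf("no omnivore template for %s", what),
             "dietscreen_config_error")
  }
}

#' Generate a personalised advice bundle for one person
#'
#' Combines diet-quality scores with blood status:
#' \itemize{
#'   \item every index component scoring below the advice threshold
#'     yields a diet-rule item;
#'   \item every micronutrient/protein compliance score below the
#'     threshold yields a diet-rule item;
#'   \item every analyte below or above its reference range yields a
#'     blood-rule item (above-range items carry supplement-review
#'     wording);
#'   \item an analyte below range while the corresponding dietary
#'     compliance score is at or above the threshold indicates a
#'     possible physiological rather than dietary cause: the item
#'     becomes a cross-rule and the bundle's `further_diagnostics`
#'     flag is set.
#' }
#' Vegetarian respondents receive vegetarian template variants where
#' defined.  Each target carries at most one item.
#'
#' @param dhd_scores One-row tibble from [score_dhd()] for the person.
#' @param nutrient_scores One-row tibble from [score_nutrients()].
#' @param status Classification rows for the person
#'   ([classify_panel()]).
#' @param diet_type `"omnivore"`, `"flexitarian"` or `"vegetarian"`.
#' @param rules Rule list from [load_advice_rules()].
#' @return List of class `advice_bundle`: `person_id`, `items` tibble
#'   (`target`, `provenance`, `text`) and `further_diagnostics` flag.
#' @export
generate_advice <- function(dhd_scores, nutrient_scores, status,
                            diet_type = c("omnivore", "flexitarian", "vegetarian"),
                            rules = load_advice_rules()) {
  diet_type <- match.arg(diet_type)
  stopifnot(nrow(dhd_scores) == 1, nrow(nutrient_scores) == 1)
  if (!identical(dhd_scores$person_id, nutrient_scores$person_id)) {
    ds_abort("diet and nutrient scores refer to different persons",
             "dietscreen_validation_error")
  }
  threshold <- rules$diet_threshold %||% 8
  items <- list()

  for (comp in names(rules$components)) {
    if (!comp %in% names(dhd_scores)) next
    if (dhd_scores[[comp]] < threshold) {
      items[[length(items) + 1]] <- tibble::tibble(
        target = comp, provenance = "diet_rule",
        text = pick_template(rules$components[[comp]], diet_type, comp)
      )
    }
  }
  for (nut in names(rules$nutrients)) {
    col <- paste0("score_", nut)
    if (!col %in% names(nutrient_scores)) next
    if (nutrient_scores[[col]] < threshold) {
      items[[length(items) + 1]] <- tibble::tibble(
        target = nut, provenance = "diet_rule",
        text = pick_template(rules$nutrients[[nut]], diet_type, nut)
      )
    }
  }

  further_diagnostics <- FALSE
  status <- status[status$status %in% c("below", "above"), , drop = FALSE]
  for (i in seq_len(nrow(status))) {
    analyte <- status$analyte[i]
    direction <- as.character(status$status[i])
    rule <- rules$analytes[[analyte]]
    if (is.null(rule)) {
      ds_abort(sprintf("no advice rule for analyte %s", analyte),
               "dietscreen_config_error")
    }
    provenance <- "blood_rule"
    if (direction == "below") {
      col <- paste0("score_", rule$nutrient)
      diet_ok <- col %in% names(nutrient_scores) &&
        nutrient_scores[[col]] >= threshold
      if (isTRUE(diet_ok)) {
        provenance <- "cross_rule"
        further_diagnostics <- TRUE
      }
    }
    items[[length(items) + 1]] <- tibble::tibble(
      target = analyte, provenance = provenance,
      text = pick_template(rule[[direction]], diet_type,
                           paste(analyte, direction))
    )
  }

  items <- if (length(items) == 0) {
    tibble::tibble(target = character(), provenance = character(),
                   text = character())
  } else {
    dplyr::distinct(dplyr::bind_rows(items), .data$target, .keep_all = TRUE)
  }
  structure(
    list(person_id = dhd_scores$person_id, diet_type = diet_type,
         items = items, further_diagnostics = further_diagnostics),
    class = "advice_bundle"
  )
}

#' @export
print.advice_bundle <- function(x, ...) {
  cat(sprintf("<advice_bundle> %s (%s): %d item(s)%s\n",
              x$person_id, x$diet_type, nrow(x$items),
              if (x$further_diagnostics) ", further diagnostics advised" else ""))
  invisible(x)
}

#' Generate advice bundles for a cohort
#'
#' @param dhd_scores Tibble from [score_dhd()] (one row per person).
#' @param nutrient_scores Tibble from [score_nutrients()].
#' @param classifications Tibble from [classify_panel()].
#' @param diet_types Tibble `person_id`, `diet_type`.
#' @param rules Rule list from [load_advice_rules()].
#' @return Named list of `advice_bundle`s keyed by person id.
#' @export
advise_cohort <- function(dhd_scores, nutrient_scores, classifications,
                          diet_types, rules = load_advice_rules()) {
  check_columns(diet_types, c("person_id", "diet_type"), "diet-type table")
  ids <- dhd_scores$person_id
  bundles <- lapply(ids, function(id) {
    dt <- diet_types$diet_type[diet_types$person_id == id]
    generate_advice(
      dhd_scores[dhd_scores$person_id == id, ],
      nutrient_scores[nutrient_scores$person_id == id, ],
      classifications[classifications$person_id == id, ],
      diet_type = if (length(dt) == 1) dt else "omnivore",
      rules = rules
    )
  })
  stats::setNames(bundles, ids)
}
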