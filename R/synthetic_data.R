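#' Default synthetic food profiles for recall simulation
#'
#' A 20-food set sized so that a simulated athlete's mean daily energy
#' intake is about 12.5 MJ (plausible for a training population, so the
#' Goldberg screen only trims genuine lognormal-tail under-reporters).
#' Eggs, shrimp and a sports drink are deliberately left unmapped to the
#' FFQ: eggs and shrimp carry substantial vitamin B12 and vitamin D, so
#' those two nutrients end up insufficiently covered and the
#' candidate-addition search has something real to find; shrimp gets a
#' long-tailed between-person distribution (an occasional extreme
#' consumer).  Values are plausible synthetic settings, not survey data.
#'
#' @return Tibble of food profiles accepted by [simulate_recalls()].
#' @export
default_food_profiles <- function() {
  nut0 <- function(...) {
    dens <- list(energy_kj = 0, protein_g = 0, fat_g = 0, carb_g = 0,
                 fibre_g = 0, vitb6_mg = 0, folate_eq_ug = 0, vitb12_ug = 0,
                 vitd_ug = 0, iron_mg = 0)
    utils::modifyList(dens, list(...))
  }
  profiles <- list(
    list(food_code = "bread_wholegrain", mean_g = 120, between_sd_g = 45, within_sd_g = 30,
         ffq_item_id = "bread_wholegrain",
         dens = nut0(energy_kj = 990, protein_g = 9, fat_g = 2, carb_g = 41,
                     fibre_g = 6.5, vitb6_mg = 0.15, folate_eq_ug = 40, iron_mg = 2.5)),
    list(food_code = "bread_white", mean_g = 60, between_sd_g = 40, within_sd_g = 25,
         ffq_item_id = "bread_white",
         dens = nut0(energy_kj = 1100, protein_g = 8, fat_g = 2, carb_g = 49,
                     fibre_g = 2.5, vitb6_mg = 0.08, folate_eq_ug = 25, iron_mg = 1)),
    list(food_code = "pasta_rice_cooked", mean_g = 180, between_sd_g = 70, within_sd_g = 60,
         ffq_item_id = "pasta_rice_white",
         dens = nut0(energy_kj = 640, protein_g = 5, fat_g = 1, carb_g = 30,
                     fibre_g = 1.5, vitb6_mg = 0.05, folate_eq_ug = 5, iron_mg = 0.5)),
    list(food_code = "potato_boiled", mean_g = 150, between_sd_g = 60, within_sd_g = 50,
         ffq_item_id = "potato",
         dens = nut0(energy_kj = 320, protein_g = 1.9, carb_g = 16, fibre_g = 1.8,
                     vitb6_mg = 0.3, folate_eq_ug = 10, iron_mg = 0.4)),
    list(food_code = "veg_mixed", mean_g = 200, between_sd_g = 80, within_sd_g = 60,
         ffq_item_id = "veg_cooked",
         dens = nut0(energy_kj = 120, protein_g = 2, carb_g = 4, fibre_g = 2.5,
                     vitb6_mg = 0.15, folate_eq_ug = 60, iron_mg = 0.8)),
    list(food_code = "fruit_fresh", mean_g = 150, between_sd_g = 70, within_sd_g = 60,
         ffq_item_id = "fruit_other",
         dens = nut0(energy_kj = 250, protein_g = 0.8, carb_g = 13, fibre_g = 2,
                     vitb6_mg = 0.1, folate_eq_ug = 20, iron_mg = 0.3)),
    list(food_code = "milk_semi", mean_g = 350, between_sd_g = 160, within_sd_g = 80,
         ffq_item_id = "milk",
         dens = nut0(energy_kj = 195, protein_g = 3.5, fat_g = 1.5, carb_g = 4.8,
                     vitb6_mg = 0.05, folate_eq_ug = 5, vitb12_ug = 0.4, vitd_ug = 0.03,
                     iron_mg = 0.05)),
    list(food_code = "yoghurt", mean_g = 150, between_sd_g = 90, within_sd_g = 60,
         ffq_item_id = "yoghurt",
         dens = nut0(energy_kj = 270, protein_g = 4, fat_g = 3, carb_g = 4.5,
                     vitb6_mg = 0.05, folate_eq_ug = 8, vitb12_ug = 0.3, vitd_ug = 0.03,
                     iron_mg = 0.05)),
    list(food_code = "cheese", mean_g = 35, between_sd_g = 20, within_sd_g = 12,
         ffq_item_id = "cheese",
         dens = nut0(energy_kj = 1500, protein_g = 24, fat_g = 31,
                     vitb6_mg = 0.05, folate_eq_ug = 25, vitb12_ug = 1.5, vitd_ug = 0.3,
                     iron_mg = 0.2)),
    list(food_code = "beef_steak", mean_g = 55, between_sd_g = 35, within_sd_g = 25,
         ffq_item_id = "beef",
         dens = nut0(energy_kj = 630, protein_g = 21, fat_g = 7,
                     vitb6_mg = 0.3, folate_eq_ug = 8, vitb12_ug = 2, vitd_ug = 0.1,
                     iron_mg = 2.3)),
    list(food_code = "chicken_fillet", mean_g = 70, between_sd_g = 40, within_sd_g = 30,
         ffq_item_id = "chicken_poultry",
         dens = nut0(energy_kj = 700, protein_g = 23, fat_g = 6,
                     vitb6_mg = 0.5, folate_eq_ug = 8, vitb12_ug = 0.4, vitd_ug = 0.2,
                     iron_mg = 0.7)),
    list(food_code = "salmon_smoked", mean_g = 15, between_sd_g = 18, within_sd_g = 8,
         ffq_item_id = "fish_fatty",
         dens = nut0(energy_kj = 750, protein_g = 20, fat_g = 11,
                     vitb6_mg = 0.5, folate_eq_ug = 10, vitb12_ug = 4, vitd_ug = 10,
                     iron_mg = 0.8)),
    list(food_code = "soft_margarine", mean_g = 25, between_sd_g = 10, within_sd_g = 6,
         ffq_item_id = "soft_margarine",
         dens = nut0(energy_kj = 2600, fat_g = 70, vitd_ug = 7.5)),
    list(food_code = "cooking_oil", mean_g = 15, between_sd_g = 8, within_sd_g = 5,
         ffq_item_id = "cooking_oil",
         dens = nut0(energy_kj = 3700, fat_g = 100)),
    list(food_code = "nuts_mixed", mean_g = 20, between_sd_g = 15, within_sd_g = 10,
         ffq_item_id = "nuts_unsalted",
         dens = nut0(energy_kj = 2600, protein_g = 20, fat_g = 55, carb_g = 8,
                     fibre_g = 7, vitb6_mg = 0.5, folate_eq_ug = 60, iron_mg = 3)),
    list(food_code = "snacks_sweet", mean_g = 70, between_sd_g = 40, within_sd_g = 35,
         ffq_item_id = "biscuits",
         dens = nut0(energy_kj = 1900, protein_g = 5, fat_g = 20, carb_g = 55,
                     fibre_g = 2, vitb6_mg = 0.05, folate_eq_ug = 10, iron_mg = 1)),
    list(food_code = "soft_drink", mean_g = 250, between_sd_g = 150, within_sd_g = 120,
         ffq_item_id = "cola_soft_drink",
         dens = nut0(energy_kj = 180, carb_g = 10.5)),
    # sports nutrition and two nutrient-dense foods left out of the FFQ
    list(food_code = "sports_drink", mean_g = 300, between_sd_g = 200, within_sd_g = 150,
         ffq_item_id = NA,
         dens = nut0(energy_kj = 120, carb_g = 7)),
    list(food_code = "egg_boiled", mean_g = 50, between_sd_g = 40, within_sd_g = 18,
         ffq_item_id = NA,
         dens = nut0(energy_kj = 540, protein_g = 13, fat_g = 9.5,
                     vitb6_mg = 0.12, folate_eq_ug = 45, vitb12_ug = 2.5, vitd_ug = 1.8,
                     iron_mg = 1.9)),
    list(food_code = "shrimp", mean_g = 4, between_sd_g = 25, within_sd_g = 3,
         ffq_item_id = NA,
         dens = nut0(energy_kj = 350, protein_g = 18,
                     vitb6_mg = 0.1, folate_eq_ug = 15, vitb12_ug = 1.3, vitd_ug = 2,
                     iron_mg = 1.6))
  )
  purrr::map_dfr(profiles, function(p) {
    tibble::tibble(
      food_code = p$food_code, mean_g = p$mean_g,
      between_sd_g = p$between_sd_g, within_sd_g = p$within_sd_g,
      ffq_item_id = p$ffq_item_id,
      !!!p$dens
    )
  })
}

# internal: lognormal draw with given arithmetic mean and sd
rlnorm_meansd <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  if (sd <= 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate multi-day 24-h recall data with known MOM ground truth
#'
#' Person-level mean daily amounts are lognormal (right-skewed,
#' nonnegative) with the requested between-person sd; day-level amounts
#' are normal around the person mean with the within-person sd,
#' truncated at zero.  Ground-truth contribution shares assume
#' independent foods: the level share of food f is its density-weighted
#' mean amount over the total, and the variance share is its squared
#' density times the between-person amount variance over the total
#' (exact when the within-person sd is 0).
#'
#' @param n_persons Number of persons.
#' @param foods Food-profile tibble ([default_food_profiles()]): columns
#'   `food_code`, `mean_g`, `between_sd_g`, `within_sd_g`, `ffq_item_id`
#'   (`NA` = unmapped) and the nutrient density columns.
#' @param n_days Recall days per person, sampled uniformly from this set
#'   (default 3-4 days).
#' @param seed Integer seed; same seed, same dataset.
#' @return List `records`, `fct`, `mapping`, `ground_truth` (tibble
#'   `nutrient`, `food_code`, `mom1_true`, `mom2_true`).
#' @export
simulate_recalls <- function(n_persons, foods = default_food_profiles(),
                             n_days = c(3, 4), seed = 1) {
  nutrients <- dietscreen_nutrients()
  check_columns(foods, c("food_code", "mean_g", "between_sd_g", "within_sd_g",
                         "ffq_item_id", nutrients), "food profiles")
  if (n_persons < 1 || any(foods$mean_g < 0) ||
      any(foods$between_sd_g < 0) || any(foods$within_sd_g < 0)) {
    ds_abort("invalid simulation settings: need n_persons >= 1 and nonnegative means/sds",
             "dietscreen_validation_error")
  }
  set.seed(seed)
  persons <- sprintf("p%04d", seq_len(n_persons))
  days_per_person <- sample(rep(n_days, length.out = max(n_persons, length(n_days))),
                            n_persons, replace = TRUE)

  records <- purrr::map_dfr(seq_len(n_persons), function(i) {
    person_means <- vapply(seq_len(nrow(foods)), function(f) {
      rlnorm_meansd(1, foods$mean_g[f], foods$between_sd_g[f])
    }, numeric(1))
    purrr::map_dfr(seq_len(days_per_person[i]), function(day) {
      amounts <- pmax(0, stats::rnorm(nrow(foods), person_means,
                                      foods$within_sd_g))
      tibble::tibble(person_id = persons[i], recall_day = day,
                     food_code = foods$food_code, amount_g = amounts)
    })
  })
  records <- records[records$amount_g > 0, ]

  fct <- foods[, c("food_code", nutrients)]
  fct$name <- foods$food_code
  mapping <- tibble::tibble(food_code = foods$food_code,
                            ffq_item_id = foods$ffq_item_id,
                            label = foods$food_code)

  ground_truth <- purrr::map_dfr(nutrients, function(nut) {
    dens <- foods[[nut]] / 100
    level <- dens * foods$mean_g
    varc <- (dens * foods$between_sd_g)^2
    tibble::tibble(
      nutrient = nut, food_code = foods$food_code,
      mom1_true = if (sum(level) > 0) 100 * level / sum(level) else NA_real_,
      mom2_true = if (sum(varc) > 0) 100 * varc / sum(varc) else NA_real_
    )
  })

  list(records = records, fct = fct, mapping = mapping,
       ground_truth = ground_truth)
}

#' Simulate FFQ responses at a controlled adherence level
#'
#' For each index component one designated driver item is set so that
#' adherence 1 hits the component's full-score intake exactly (total
#' 160 under the default configuration) and adherence 0 hits the
#' worst-scoring intake (total 0); intermediate adherence interpolates
#' the intake stochastically per person and component via a Beta draw
#' centred near the requested level.  All other items are answered zero.
#'
#' @param n Number of respondents.
#' @param adherence Target adherence in \[0, 1\].
#' @param seed Integer seed.
#' @param ffq_def FFQ definition ([load_ffq_definition()]).
#' @param components Component definitions
#'   ([load_component_definitions()]).
#' @return Tibble `person_id`, `item_id`, `freq_per_week`,
#'   `amount_per_occasion` covering every item for every person.
#' @export
simulate_ffq <- function(n, adherence, seed = 1,
                         ffq_def = load_ffq_definition(),
                         components = load_component_definitions()) {
  if (adherence < 0 || adherence > 1) {
    ds_abort("adherence must lie in [0, 1]", "dietscreen_validation_error")
  }
  set.seed(seed)
  items <- ffq_def$items
  persons <- sprintf("f%04d", seq_len(n))
  fat_total <- 40  # g/day split between soft and solid fats

  base <- tidyr::expand_grid(person_id = persons, item_id = items$item_id)
  base$freq_per_week <- 0
  base$amount_per_occasion <- 0

  draw_b <- function(n) {
    if (adherence == 1) rep(1, n)
    else if (adherence == 0) rep(0, n)
    else stats::rbeta(n, 1 + 8 * adherence, 1 + 8 * (1 - adherence))
  }

  set_item <- function(base, item, freq, amount) {
    idx <- match(paste(persons, item), paste(base$person_id, base$item_id))
    base$freq_per_week[idx] <- freq
    base$amount_per_occasion[idx] <- amount
    base
  }

  for (k in seq_len(nrow(components))) {
    def <- components[k, ]
    comp_items <- items[items$component %in% def$id, ]
    b <- draw_b(n)
    if (def$kind == "ratio") {
      soft <- comp_items$item_id[comp_items$ratio_role %in% "soft"][1]
      solid <- comp_items$item_id[comp_items$ratio_role %in% "solid"][1]
      base <- set_item(base, soft, 7, b * fat_total /
                         comp_items$weight[match(soft, comp_items$item_id)])
      base <- set_item(base, solid, 7, (1 - b) * fat_total /
                         comp_items$weight[match(solid, comp_items$item_id)])
      next
    }
    driver <- comp_items[1, ]
    perfect <- switch(def$kind,
                      adequacy = def$threshold,
                      moderation = 0,
                      optimum = (def$opt_low + def$opt_high) / 2,
                      binary = 0)
    worst <- switch(def$kind,
                    adequacy = 0,
                    moderation = def$upper,
                    optimum = 0,
                    binary = def$cutoff + 7)
    level <- worst + b * (perfect - worst)
    if (def$basis == "frequency") {
      base <- set_item(base, driver$item_id, level / driver$weight, 50)
    } else {
      base <- set_item(base, driver$item_id, 7, level / driver$weight)
    }
  }
  base
}

#' Simulate blood panels at controlled deficiency prevalence
#'
#' Draws each analyte's classification (below/within/above) from the
#' target prevalences and places the concentration uniformly inside the
#' corresponding segment of the reference interval, so realised
#' prevalence converges to the targets as n grows.
#'
#' @param n_male,n_female Persons per sex.
#' @param prevalence Named list: `analyte -> list(below =, above =)`
#'   target probabilities (missing analytes get 0/0).
#' @param ranges Reference ranges ([load_reference_ranges()]).
#' @param seed Integer seed.
#' @return Tibble in the panel layout accepted by [classify_panel()].
#' @export
simulate_panels <- function(n_male, n_female, prevalence = list(),
                            ranges = load_reference_ranges(), seed = 1) {
  bad <- vapply(prevalence, function(p) {
    pb <- p$below %||% 0; pa <- p$above %||% 0
    pb < 0 || pa < 0 || pb + pa > 1
  }, logical(1))
  if (any(bad)) {
    ds_abort("prevalences must be in [0,1] and sum to at most 1 per analyte",
             "dietscreen_validation_error")
  }
  set.seed(seed)
  sexes <- c(rep("male", n_male), rep("female", n_female))
  persons <- sprintf("b%04d", seq_along(sexes))
  panels <- tibble::tibble(person_id = persons, sex = sexes)
  for (analyte in panel_analytes()) {
    p <- prevalence[[analyte]] %||% list()
    pb <- p$below %||% 0
    pa <- p$above %||% 0
    values <- vapply(seq_along(sexes), function(i) {
      r <- ranges[ranges$analyte == analyte &
                    ranges$sex %in% c(sexes[i], "any"), ][1, ]
      category <- sample(c("below", "within", "above"), 1,
                         prob = c(pb, 1 - pb - pa, pa))
      switch(category,
             below = stats::runif(1, 0.5 * r$low, 0.99 * r$low),
             within = stats::runif(1, r$low, r$high),
             above = stats::runif(1, 1.01 * r$high, 1.5 * r$high))
    }, numeric(1))
    panels[[analyte]] <- values
  }
  panels
}

#' Simulate paired baseline/follow-up total scores with a known shift
#'
#' Baseline totals are normal around `baseline_mean` (clipped to the
#' index range 0-160); follow-up totals add a normal change of mean
#' `shift` and sd `sd_diff`, clipped likewise.
#'
#' @param n Number of persons (>= 2).
#' @param shift True mean change in points.
#' @param sd_diff Sd of the change in points.
#' @param baseline_mean,baseline_sd Baseline total distribution.
#' @param seed Integer seed.
#' @return Tibble `person_id`, `baseline_total`, `followup_total`.
#' @export
simulate_paired <- function(n, shift, sd_diff, baseline_mean = 110,
                            baseline_sd = 15, seed = 1) {
  if (n < 2) {
    ds_abort("need at least 2 persons", "dietscreen_validation_error")
  }
  set.seed(seed)
  baseline <- pmin(160, pmax(0, stats::rnorm(n, baseline_mean, baseline_sd)))
  followup <- pmin(160, pmax(0, baseline + stats::rnorm(n, shift, sd_diff)))
  tibble::tibble(person_id = sprintf("s%04d", seq_len(n)),
                 baseline_total = baseline, followup_total = followup)
}
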