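rules <- load_advice_rules()
defs <- load_component_definitions()

# score rows with every component / nutrient at a given level
make_scores <- function(person = "a1", level = 10) {
  comp <- stats::setNames(as.list(rep(level, 16)), defs$id)
  tibble::as_tibble(c(list(person_id = person), comp,
                      list(total = 16 * level)))
}
make_nutrient_scores <- function(person = "a1", level = 10) {
  nuts <- paste0("score_", names(rules$nutrients))
  tibble::as_tibble(c(list(person_id = person),
                      stats::setNames(as.list(rep(level, length(nuts))), nuts)))
}
status_one <- function(person, analyte, status) {
  tibble::tibble(person_id = person, sex = "male", analyte = analyte,
                 value = 1,
                 status = factor(status,
                                 levels = c("below", "within", "above", "missing")))
}
no_status <- function(person = "a1") status_one(person, "vitd_nmol_l", "within")[0, ]

test_that("a perfect profile produces an empty bundle without flags", {
  b <- generate_advice(make_scores(), make_nutrient_scores(), no_status(),
                       "omnivore", rules)
  expect_equal(nrow(b$items), 0)
  expect_false(b$further_diagnostics)
})

test_that("low blood value with poor diet gives dietary advice, not diagnostics", {
  ns <- make_nutrient_scores()
  ns$score_vitd_ug <- 2
  b <- generate_advice(make_scores(), ns,
                       status_one("a1", "vitd_nmol_l", "below"),
                       "omnivore", rules)
  expect_true("vitd_nmol_l" %in% b$items$target)
  expect_true("vitd_ug" %in% b$items$target)   # compliance score below threshold
  expect_equal(b$items$provenance[b$items$target == "vitd_nmol_l"], "blood_rule")
  expect_false(b$further_diagnostics)
})

test_that("low blood value despite adequate diet raises the diagnostics flag", {
  b <- generate_advice(make_scores(), make_nutrient_scores(),
                       status_one("a1", "vitd_nmol_l", "below"),
                       "omnivore", rules)
  expect_true(b$further_diagnostics)
  expect_equal(b$items$provenance[b$items$target == "vitd_nmol_l"], "cross_rule")
})

test_that("above-range values yield a supplement-review caution", {
  b <- generate_advice(make_scores(), make_nutrient_scores(),
                       status_one("a1", "vitb6_nmol_l", "above"),
                       "omnivore", rules)
  item <- b$items[b$items$target == "vitb6_nmol_l", ]
  expect_equal(item$provenance, "blood_rule")
  expect_match(item$text, "supplement")
  expect_false(b$further_diagnostics)
})

test_that("vegetarians receive the vegetarian template variant where defined", {
  scores <- make_scores()
  scores$fish <- 2
  veg <- generate_advice(scores, make_nutrient_scores(), no_status(),
                         "vegetarian", rules)
  omn <- generate_advice(scores, make_nutrient_scores(), no_status(),
                         "omnivore", rules)
  expect_false(veg$items$text[veg$items$target == "fish"] ==
                 omn$items$text[omn$items$target == "fish"])
  # flexitarians fall back to the omnivore wording
  flex <- generate_advice(scores, make_nutrient_scores(), no_status(),
                          "flexitarian", rules)
  expect_equal(flex$items$text[flex$items$target == "fish"],
               omn$items$text[omn$items$target == "fish"])
})

test_that("every component and nutrient target can fire a rule", {
  for (comp in defs$id) {
    scores <- make_scores()
    scores[[comp]] <- 0
    b <- generate_advice(scores, make_nutrient_scores(), no_status(),
                         "omnivore", rules)
    expect_equal(b$items$target, comp)
  }
  for (nut in names(rules$nutrients)) {
    ns <- make_nutrient_scores()
    ns[[paste0("score_", nut)]] <- 0
    b <- generate_advice(make_scores(), ns, no_status(), "omnivore", rules)
    expect_equal(b$items$target, nut)
  }
})

test_that("advice is deterministic and monotone in component scores", {
  scores <- make_scores(level = 5)
  ns <- make_nutrient_scores(level = 5)
  st <- status_one("a1", "ferritin_ug_l", "below")
  b1 <- generate_advice(scores, ns, st, "omnivore", rules)
  b2 <- generate_advice(scores, ns, st, "omnivore", rules)
  expect_equal(b1$items, b2$items)
  expect_equal(anyDuplicated(b1$items$target), 0)

  improved <- scores
  improved$vegetables <- 10
  b3 <- generate_advice(improved, ns, st, "omnivore", rules)
  expect_false("vegetables" %in% b3$items$target)
  expect_true(all(setdiff(b3$items$target, "vegetables") %in% b1$items$target))
})

test_that("cohort advice keys bundles by person and respects diet types", {
  scores <- dplyr::bind_rows(make_scores("a1"), make_scores("a2"))
  scores$fish <- 2
  ns <- dplyr::bind_rows(make_nutrient_scores("a1"), make_nutrient_scores("a2"))
  dt <- tibble::tibble(person_id = c("a1", "a2"),
                       diet_type = c("vegetarian", "omnivore"))
  bundles <- advise_cohort(scores, ns, no_status(), dt, rules)
  expect_named(bundles, c("a1", "a2"))
  expect_match(bundles$a1$items$text[bundles$a1$items$target == "fish"], "algae")
})
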