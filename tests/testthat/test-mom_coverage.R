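# mapping helper: map the given foods, leave the rest unmapped
map_only <- function(foods, mapped) {
  tibble::tibble(food_code = foods,
                 ffq_item_id = ifelse(foods %in% mapped, "item", NA),
                 label = foods)
}

test_that("MOM1 matches the hand-arithmetic example and basic invariances", {
  pi <- two_person_example()
  m1 <- mom1(pi, "iron_mg")
  expect_equal(unname(m1["f1"]), 100 * 80 / 300, tolerance = 1e-12)
  expect_equal(unname(m1["f2"]), 100 * 220 / 300, tolerance = 1e-12)
  expect_equal(sum(m1), 100, tolerance = 1e-6)

  # single person, single food carries everything
  single <- compute_person_intake(
    tibble::tibble(person_id = "p1", recall_day = 1,
                   food_code = "only", amount_g = 120),
    make_fct_row("only", iron_mg = 3)
  )
  expect_equal(unname(mom1(single, "iron_mg")), 100)

  # duplicating every person leaves the ratios unchanged
  fx <- random_recalls(seed = 11)
  doubled <- dplyr::bind_rows(
    fx$records, dplyr::mutate(fx$records, person_id = paste0(person_id, "_b"))
  )
  expect_equal(mom1(compute_person_intake(doubled, fx$fct), "iron_mg"),
               mom1(compute_person_intake(fx$records, fx$fct), "iron_mg"))
})

test_that("MOM2 assigns all between-person variance to the varying food", {
  pi <- two_person_example()
  m2 <- mom2(pi, "iron_mg")
  expect_equal(unname(m2["f1"]), 0, tolerance = 1e-9)
  expect_equal(unname(m2["f2"]), 100, tolerance = 1e-9)
})

test_that("MOM2 equals the brute-force covariance decomposition on small instances", {
  for (seed in 1:4) {
    fx <- random_recalls(n_persons = 8, n_foods = 5, n_days = 2, seed = seed)
    pi <- compute_person_intake(fx$records, fx$fct)
    for (nut in c("energy_kj", "vitd_ug")) {
      m2 <- mom2(pi, nut)
      contrib <- tidyr::pivot_wider(
        pi$contributions[pi$contributions$nutrient == nut,
                         c("person_id", "food_code", "mean_daily")],
        names_from = food_code, values_from = mean_daily, values_fill = 0
      )
      mat <- as.matrix(contrib[, -1])
      oracle <- oracle_mom2(mat)
      expect_equal(m2[names(oracle)], oracle, tolerance = 1e-9)
      expect_equal(sum(m2), 100, tolerance = 1e-6)
    }
  }
})

test_that("degenerate inputs raise classed errors", {
  pi <- two_person_example()
  expect_error(mom1(pi, "vitd_ug"),  # all-zero intake of that nutrient
               class = "dietscreen_undefined_statistic_error")

  const <- compute_person_intake(
    tibble::tibble(person_id = c("p1", "p2"), recall_day = 1,
                   food_code = "f", amount_g = 100),
    make_fct_row("f", iron_mg = 2)
  )
  expect_error(mom2(const, "iron_mg"),
               class = "dietscreen_degenerate_variance_error")
})

test_that("sum scores cover full, empty and partial mappings", {
  pi <- two_person_example()
  mom <- mom_table(pi, "iron_mg")
  foods <- c("f1", "f2")

  full <- sum_scores(mom, map_only(foods, foods))
  expect_equal(full$mom1_sum, 100, tolerance = 1e-6)
  expect_equal(full$mom2_sum, 100, tolerance = 1e-6)

  none <- sum_scores(mom, map_only(foods, character()))
  expect_equal(none$mom1_sum, 0)
  expect_equal(none$mom2_sum, 0)

  only_f2 <- sum_scores(mom, map_only(foods, "f2"))
  expect_equal(only_f2$mom1_sum, 100 * 220 / 300, tolerance = 1e-9)
  expect_equal(only_f2$mom2_sum, 100, tolerance = 1e-9)

  expect_error(sum_scores(mom, map_only("f1", "f1")),
               "f2", class = "dietscreen_mapping_gap_error")
})

test_that("the coverage decision is inclusive at the threshold", {
  sums <- tibble::tibble(nutrient = c("a", "b", "c"),
                         mom1_sum = c(80, 76.2, 90),
                         mom2_sum = c(80, 39.1, 79.9))
  dec <- coverage_decision(sums)
  expect_equal(dec$sufficient, c(TRUE, FALSE, FALSE))
  expect_true(all(coverage_decision(sums, threshold = 0)$sufficient))
})

test_that("candidate search applies the >=1 % and/or rule to unmapped foods only", {
  mom <- tibble::tibble(
    nutrient = "vitb12_ug",
    food_code = c("mapped_big", "egg", "shrimp", "trace"),
    mom1 = c(70, 0.2, 2, 0.5),
    mom2 = c(60, 3, 1.5, 0.5)
  )
  mapping <- map_only(mom$food_code, "mapped_big")
  cand <- candidate_additions(mom, mapping)
  # egg qualifies through MOM2 alone (the and/or rule); trace fails both
  expect_setequal(cand$food_code, c("egg", "shrimp"))
  # ordered by max(mom1, mom2) descending
  expect_equal(cand$food_code, c("egg", "shrimp"))

  expect_equal(nrow(candidate_additions(mom, map_only(mom$food_code,
                                                      mom$food_code))), 0)
  # lowering min_pct never removes a candidate
  cand_low <- candidate_additions(mom, mapping, min_pct = 0.1)
  expect_true(all(cand$food_code %in% cand_low$food_code))
})

test_that("recomputation with additions is exactly additive", {
  pi <- two_person_example()
  mom <- mom_table(pi, "iron_mg")
  mapping <- map_only(c("f1", "f2"), "f2")

  base <- sum_scores(mom, mapping)
  added <- recompute_with_additions(mom, mapping, "f1")
  expect_equal(added$mom1_sum - base$mom1_sum,
               mom$mom1[mom$food_code == "f1"], tolerance = 1e-12)
  expect_equal(added$mom1_sum, 100, tolerance = 1e-9)  # completion
  expect_equal(added$mom2_sum, 100, tolerance = 1e-9)

  expect_equal(recompute_with_additions(mom, mapping, character()), base)
  expect_error(recompute_with_additions(mom, mapping, "f2"),
               class = "dietscreen_validation_error")
})

test_that("the full coverage report searches candidates only for failing nutrients", {
  sim <- simulate_recalls(60, seed = 19)
  pi <- compute_person_intake(sim$records, sim$fct)
  rep <- coverage_report(pi, sim$mapping,
                         nutrients = c("energy_kj", "vitd_ug", "vitb12_ug"))
  ok <- rep$report$nutrient[rep$report$sufficient]
  expect_true(all(is.na(rep$report$mom1_sum_with_candidates[
    rep$report$nutrient %in% ok])))
  failing <- setdiff(rep$report$nutrient, ok)
  expect_true(all(rep$candidates$nutrient %in% failing))
  # post-addition sums never drop below the originals
  f <- rep$report[!rep$report$sufficient, ]
  expect_true(all(f$mom1_sum_with_candidates >= f$mom1_sum - 1e-9))
})
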