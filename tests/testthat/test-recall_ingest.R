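test_that("a minimal one-row recall file parses against a matching table", {
  dir <- withr::local_tempdir()
  readr::write_csv(
    tibble::tibble(person_id = "p1", recall_day = 1,
                   food_code = "salmon_smoked", amount_g = 50),
    file.path(dir, "recalls.csv")
  )
  readr::write_csv(make_fct_row("salmon_smoked", energy_kj = 750, vitd_ug = 10),
                   file.path(dir, "fct.csv"))
  loaded <- load_recalls(file.path(dir, "recalls.csv"), file.path(dir, "fct.csv"))
  expect_equal(nrow(loaded$records), 1)
  expect_equal(loaded$records$amount_g, 50)
})

test_that("schema, validation and unresolved-food errors are specific", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(person_id = "p1", recall_day = 1,
                                  food_code = "mystery", amount_g = 10),
                   file.path(dir, "recalls.csv"))
  readr::write_csv(make_fct_row("salmon_smoked"), file.path(dir, "fct.csv"))
  expect_error(
    load_recalls(file.path(dir, "recalls.csv"), file.path(dir, "fct.csv")),
    "mystery", class = "dietscreen_unresolved_food_error"
  )

  readr::write_csv(tibble::tibble(person_id = "p1", recall_day = 1,
                                  food_code = "salmon_smoked", amount_g = -5),
                   file.path(dir, "neg.csv"))
  expect_error(
    load_recalls(file.path(dir, "neg.csv"), file.path(dir, "fct.csv")),
    "row", class = "dietscreen_validation_error"
  )

  readr::write_csv(tibble::tibble(person_id = "p1", recall_day = 1),
                   file.path(dir, "short.csv"))
  expect_error(
    load_recalls(file.path(dir, "short.csv"), file.path(dir, "fct.csv")),
    "food_code", class = "dietscreen_schema_error"
  )
})

test_that("a 3-person x 3-day x 5-food fixture round-trips write -> read unchanged", {
  fx <- random_recalls(n_persons = 3, n_foods = 5, n_days = 3, seed = 21)
  dir <- withr::local_tempdir()
  write_recalls(fx$records, fx$fct,
                file.path(dir, "r.csv"), file.path(dir, "f.csv"))
  back <- load_recalls(file.path(dir, "r.csv"), file.path(dir, "f.csv"))
  expect_equal(as.data.frame(back$records), as.data.frame(fx$records))
  expect_equal(as.data.frame(back$fct), as.data.frame(fx$fct))
})

test_that("kcal energy input is converted to kJ", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(person_id = "p1", recall_day = 1,
                                  food_code = "a", amount_g = 100),
                   file.path(dir, "r.csv"))
  readr::write_csv(make_fct_row("a", energy_kj = 100),  # declared as kcal
                   file.path(dir, "f.csv"))
  loaded <- load_recalls(file.path(dir, "r.csv"), file.path(dir, "f.csv"),
                         energy_unit = "kcal")
  expect_equal(loaded$fct$energy_kj, 418.4)
})

test_that("single-food and multi-day intakes follow the hand arithmetic", {
  fct <- make_fct_row("f", iron_mg = 2)
  one_day <- tibble::tibble(person_id = "p1", recall_day = 1,
                            food_code = "f", amount_g = 100)
  pi1 <- compute_person_intake(one_day, fct)
  iron <- pi1$totals[pi1$totals$nutrient == "iron_mg", ]
  expect_equal(iron$intake, 2)
  contrib <- pi1$contributions[pi1$contributions$nutrient == "iron_mg", ]
  expect_equal(contrib$mean_daily / iron$intake, 1)  # single food = 100 %

  two_days <- tibble::tibble(person_id = "p1", recall_day = c(1, 2),
                             food_code = "f", amount_g = c(100, 300))
  pi2 <- compute_person_intake(two_days, fct)
  expect_equal(pi2$totals$intake[pi2$totals$nutrient == "iron_mg"], 4)
})

test_that("duplicate (person, day, food) rows are summed before conversion", {
  fct <- make_fct_row("f", iron_mg = 2)
  recs <- tibble::tibble(person_id = "p1", recall_day = 1,
                         food_code = "f", amount_g = c(60, 40))
  pi <- compute_person_intake(recs, fct)
  expect_equal(pi$totals$intake[pi$totals$nutrient == "iron_mg"], 2)
  expect_equal(nrow(pi$contributions[pi$contributions$nutrient == "iron_mg", ]), 1)
})

test_that("totals match an independent row-by-row summation oracle", {
  fx <- random_recalls(n_persons = 5, n_foods = 4, n_days = 3, seed = 33)
  pi <- compute_person_intake(fx$records, fx$fct)
  for (nut in c("energy_kj", "iron_mg", "vitb12_ug")) {
    oracle <- oracle_person_totals(fx$records, fx$fct, nut)
    got <- pi$totals[pi$totals$nutrient == nut, ]
    expect_equal(got$intake[match(names(oracle), got$person_id)],
                 unname(oracle), tolerance = 1e-9)
  }
})

test_that("contributions conserve totals, survive shuffling, and scale linearly", {
  fx <- random_recalls(seed = 7)
  pi <- compute_person_intake(fx$records, fx$fct)

  sums <- dplyr::summarise(
    dplyr::group_by(pi$contributions, person_id, nutrient),
    s = sum(mean_daily), .groups = "drop"
  )
  merged <- dplyr::inner_join(sums, pi$totals, by = c("person_id", "nutrient"))
  expect_true(all(abs(merged$s - merged$intake) <=
                    1e-9 * pmax(abs(merged$intake), 1)))

  shuffled <- fx$records[sample(nrow(fx$records)), ]
  pi_shuf <- compute_person_intake(shuffled, fx$fct)
  expect_equal(dplyr::arrange(pi_shuf$totals, person_id, nutrient),
               dplyr::arrange(pi$totals, person_id, nutrient))

  doubled <- dplyr::mutate(fx$records, amount_g = 2 * amount_g)
  pi_dbl <- compute_person_intake(doubled, fx$fct)
  expect_equal(dplyr::arrange(pi_dbl$totals, person_id, nutrient)$intake,
               2 * dplyr::arrange(pi$totals, person_id, nutrient)$intake)
})

test_that("a missing nutrient density is an error, not an imputed zero", {
  fct <- make_fct_row("f", iron_mg = 2)
  fct$vitd_ug <- NA_real_
  recs <- tibble::tibble(person_id = "p1", recall_day = 1,
                         food_code = "f", amount_g = 100)
  expect_error(compute_person_intake(recs, fct),
               class = "dietscreen_validation_error")
})
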