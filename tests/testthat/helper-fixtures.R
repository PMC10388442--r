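# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately written as plain loops / closed forms, not via
# the package's own code paths.

nutrient_cols <- dietscreen_nutrients()

# composition row with every nutrient defaulting to zero
make_fct_row <- function(food_code, ...) {
  dens <- stats::setNames(as.list(rep(0, length(nutrient_cols))), nutrient_cols)
  dens <- utils::modifyList(dens, list(...))
  tibble::tibble(food_code = food_code, name = food_code, !!!dens)
}

# two-person fixture reproducing the worked MOM example: food f1
# contributes 40 and 40 units, food f2 contributes 60 and 160
# (iron density 100 mg/100 g makes contribution equal grams eaten)
two_person_example <- function() {
  fct <- dplyr::bind_rows(
    make_fct_row("f1", iron_mg = 100, energy_kj = 100),
    make_fct_row("f2", iron_mg = 100, energy_kj = 100)
  )
  records <- tibble::tibble(
    person_id = c("p1", "p1", "p2", "p2"),
    recall_day = 1,
    food_code = c("f1", "f2", "f1", "f2"),
    amount_g = c(40, 60, 40, 160)
  )
  compute_person_intake(records, fct)
}

# random multi-person recall fixture with reproducible content
random_recalls <- function(n_persons = 5, n_foods = 4, n_days = 3, seed = 1) {
  set.seed(seed)
  foods <- sprintf("food%02d", seq_len(n_foods))
  fct <- purrr::map_dfr(foods, function(f) {
    make_fct_row(f,
                 energy_kj = runif(1, 100, 2000), protein_g = runif(1, 0, 25),
                 fat_g = runif(1, 0, 30), carb_g = runif(1, 0, 60),
                 fibre_g = runif(1, 0, 10), vitb6_mg = runif(1, 0, 1),
                 folate_eq_ug = runif(1, 0, 150), vitb12_ug = runif(1, 0, 5),
                 vitd_ug = runif(1, 0, 12), iron_mg = runif(1, 0, 5))
  })
  records <- tidyr::expand_grid(
    person_id = sprintf("p%02d", seq_len(n_persons)),
    recall_day = seq_len(n_days),
    food_code = foods
  )
  records$amount_g <- round(runif(nrow(records), 0, 300), 1)
  list(records = records, fct = fct)
}

# spreadsheet-style oracle: per-person mean daily nutrient totals by
# explicit row iteration, no grouping verbs
oracle_person_totals <- function(records, fct, nutrient) {
  persons <- unique(records$person_id)
  sapply(persons, function(p) {
    rows <- records[records$person_id == p, ]
    days <- unique(rows$recall_day)
    day_sums <- sapply(days, function(d) {
      dr <- rows[rows$recall_day == d, ]
      s <- 0
      for (i in seq_len(nrow(dr))) {
        dens <- fct[[nutrient]][fct$food_code == dr$food_code[i]]
        s <- s + dr$amount_g[i] / 100 * dens
      }
      s
    })
    mean(day_sums)
  })
}

# brute-force MOM2 from the full person x food contribution matrix via
# explicit covariance sums
oracle_mom2 <- function(contrib_matrix) {
  n <- nrow(contrib_matrix)
  total <- rowSums(contrib_matrix)
  tbar <- mean(total)
  var_t <- sum((total - tbar)^2) / (n - 1)
  shares <- apply(contrib_matrix, 2, function(x) {
    sum((x - mean(x)) * (total - tbar)) / (n - 1) / var_t
  })
  100 * shares
}

# closed-form paired t oracle
oracle_paired_t <- function(baseline, followup) {
  d <- followup - baseline
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# exhaustive signed-rank oracle (tie-free differences, zeros dropped):
# enumerates all sign assignments of the ranks to get the exact two-sided p
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  ranks <- rank(abs(d))
  v_obs <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), m))
  v_all <- as.matrix(signs) %*% ranks
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  list(V = v_obs, p = min(p, 1))
}

# minimal blood panel tibble
make_panel <- function(person_id, sex, ...) {
  vals <- stats::setNames(as.list(rep(NA_real_, length(panel_analytes()))),
                          panel_analytes())
  vals <- utils::modifyList(vals, list(...))
  tibble::tibble(person_id = person_id, sex = sex, !!!vals)
}

# FFQ response covering every item at zero, with selected overrides
ffq_response <- function(person_id = "x1", set = list()) {
  items <- load_ffq_definition()$items$item_id
  resp <- tibble::tibble(person_id = person_id, item_id = items,
                         freq_per_week = 0, amount_per_occasion = 0)
  for (it in names(set)) {
    i <- resp$item_id == it
    resp$freq_per_week[i] <- set[[it]][1]
    resp$amount_per_occasion[i] <- set[[it]][2]
  }
  resp
}
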