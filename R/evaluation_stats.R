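#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with
#' the sample mean and standard deviation (parameters estimated, no
#' Lilliefors correction; the choice is recorded in the result).  The
#' sample is called normal when p >= 0.05.
#'
#' @param values Numeric sample, n >= 3, non-constant.
#' @return List `statistic`, `p`, `normal`, `method`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    ds_abort("normality check needs at least 3 values",
             "dietscreen_validation_error")
  }
  if (stats::sd(values) == 0) {
    ds_abort("constant sample: normality undefined",
             "dietscreen_degenerate_sample_error")
  }
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = stats::sd(values))
  )
  list(statistic = unname(ks$statistic), p = ks$p.value,
       normal = ks$p.value >= 0.05,
       method = "one-sample KS vs normal(mean, sd) with estimated parameters (uncorrected)")
}

#' Paired t-test on diet-quality total scores
#'
#' Two-sided paired t-test of follow-up minus baseline totals.  When the
#' differences have zero variance the closed-form statistic is undefined
#' and the result is flagged degenerate instead of raising.
#'
#' @param pairs Tibble `person_id`, `baseline_total`, `followup_total`.
#' @return List `n`, `mean_baseline`, `mean_followup`, `mean_diff`, `t`,
#'   `df`, `p`, `degenerate`.
#' @export
paired_total_test <- function(pairs) {
  check_columns(pairs, c("person_id", "baseline_total", "followup_total"),
                "paired scores")
  if (nrow(pairs) < 2) {
    ds_abort("paired test needs at least 2 pairs",
             "dietscreen_validation_error")
  }
  d <- pairs$followup_total - pairs$baseline_total
  out <- list(
    n = nrow(pairs),
    mean_baseline = mean(pairs$baseline_total),
    mean_followup = mean(pairs$followup_total),
    mean_diff = mean(d)
  )
  if (stats::sd(d) == 0 && mean(d) == 0) {
    # no change for anyone: no evidence against the null
    c(out, list(t = 0, df = nrow(pairs) - 1, p = 1, degenerate = FALSE))
  } else if (stats::sd(d) == 0) {
    # constant nonzero shift: the statistic is undefined
    c(out, list(t = NA_real_, df = nrow(pairs) - 1, p = NA_real_,
                degenerate = TRUE))
  } else {
    tt <- stats::t.test(pairs$followup_total, pairs$baseline_total,
                        paired = TRUE)
    c(out, list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, degenerate = FALSE))
  }
}

#' Wilcoxon signed-rank tests per index component
#'
#' Compares each component (and nutrient score, if present) between
#' baseline and follow-up with a two-sided Wilcoxon signed-rank test.
#' Zero differences are dropped before ranking (classic signed-rank
#' policy, recorded in the output); a component whose differences are
#' all zero is skipped with `skipped = TRUE`.
#'
#' @param baseline,followup Score tibbles keyed by `person_id` with the
#'   same score columns (e.g. from [score_dhd()]).
#' @param columns Score columns to test (default: shared numeric columns
#'   except totals).
#' @param alpha Significance level used for the `significant` flag.
#' @return Tibble `component`, `n_nonzero`, `V`, `p`, `significant`,
#'   `skipped`, plus attribute `zero_policy`.
#' @export
component_tests <- function(baseline, followup, columns = NULL, alpha = 0.05) {
  merged <- dplyr::inner_join(baseline, followup, by = "person_id",
                              suffix = c("_b", "_f"))
  if (nrow(merged) < 2) {
    ds_abort("component tests need at least 2 pairs",
             "dietscreen_validation_error")
  }
  if (is.null(columns)) {
    columns <- setdiff(intersect(names(baseline), names(followup)),
                       c("person_id", "total"))
    columns <- columns[vapply(baseline[columns], is.numeric, logical(1))]
  }
  res <- purrr::map_dfr(columns, function(col) {
    d <- merged[[paste0(col, "_f")]] - merged[[paste0(col, "_b")]]
    d <- d[!is.na(d)]
    nz <- d[d != 0]
    if (length(nz) == 0) {
      return(tibble::tibble(component = col, n_nonzero = 0L,
                            V = NA_real_, p = NA_real_,
                            significant = FALSE, skipped = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = NULL))
    tibble::tibble(component = col, n_nonzero = length(nz),
                   V = unname(wt$statistic), p = wt$p.value,
                   significant = wt$p.value < alpha, skipped = FALSE)
  })
  attr(res, "zero_policy") <- "zero differences dropped before ranking"
  res
}

#' Summarise satisfaction-questionnaire responses
#'
#' Per-question category counts with integer percentages (rounded half
#' away from zero, so 20 of 29 prints as 69 %); blank answers are
#' excluded from that question's denominator.  The overall grade (0-10
#' scale) is summarised as mean and sd.
#'
#' @param responses Tibble: `person_id`, `grade` (numeric 0-10, may be
#'   `NA`), and one character column per question (`NA` = no answer).
#' @return List `questions` (tibble `question`, `answer`, `n`,
#'   `n_answered`, `pct`) and `grade` (list `n`, `mean`, `sd`).
#' @export
satisfaction_summary <- function(responses) {
  if (nrow(responses) == 0) {
    ds_abort("no satisfaction responses", "dietscreen_validation_error")
  }
  question_cols <- setdiff(names(responses), c("person_id", "grade"))
  questions <- purrr::map_dfr(question_cols, function(q) {
    answered <- responses[[q]][!is.na(responses[[q]]) & responses[[q]] != ""]
    if (length(answered) == 0) {
      return(tibble::tibble(question = q, answer = NA_character_,
                            n = 0L, n_answered = 0L, pct = NA_real_))
    }
    counts <- table(answered)
    tibble::tibble(
      question = q,
      answer = names(counts),
      n = as.integer(counts),
      n_answered = length(answered),
      pct = round_half_up(100 * as.integer(counts) / length(answered))
    )
  })
  grades <- responses$grade[!is.na(responses$grade)]
  if (any(grades < 0 | grades > 10)) {
    ds_abort("grades must lie in [0, 10]", "dietscreen_validation_error")
  }
  list(
    questions = questions,
    grade = list(n = length(grades),
                 mean = if (length(grades)) mean(grades) else NA_real_,
                 sd = if (length(grades) > 1) stats::sd(grades) else
                   if (length(grades) == 1) 0 else NA_real_)
  )
}
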