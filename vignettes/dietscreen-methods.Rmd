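---
title: "Methods behind dietscreen: FFQ coverage, diet-quality scoring and screening advice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind dietscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietscreen)
```

This vignette documents the models, numerical choices and limitations of the
pipeline: what each stage assumes, which parameters matter and why the
defaults are what they are, and what the synthetic-data generators do and do
not emulate.

## From recall records to person-level intake

A 24-h recall dataset is a table of (person, recall day, food, grams).
Each food's nutrient contribution on a day is `amount/100 × density`
(densities per 100 g from the food-composition table); contributions are
summed within a day and averaged over the person's 3–4 recall days.
Duplicate (person, day, food) rows are summed before conversion because a
recall lists foods per eating occasion. Two deliberate strictness choices:

- a food code missing from the composition table is an error, never a
  dropped row, and
- a missing nutrient density is an error, never an imputed zero — a silent
  zero would deflate that food's contribution to the level statistic in a
  way no downstream check could detect.

Energy is carried in kJ internally (the plausibility screen needs MJ/day);
kcal input is accepted with a declared unit flag (1 kcal = 4.184 kJ).

## The coverage statistics

Write `x_if` for person *i*'s mean daily contribution of food *f* to a
nutrient and `T_i = Σ_f x_if` for the total. The two per-food statistics
are

- **level share**: `MOM1_f = 100 · Σ_i x_if / Σ_i T_i`, nonnegative, summing
  to 100 over foods;
- **variance share**: `MOM2_f = 100 · Cov(x_f, T)/Var(T)` with sample
  covariance/variance over persons.

The variance share uses the exact additive identity
`Var(T) = Σ_f Cov(x_f, T)`, so shares always sum to 100 and a food that
covaries negatively with the total carries a negative share. A stepwise
regression (cumulative-R²) definition of variance shares exists in the
literature; it is order-dependent and does not decompose exactly, so the
covariance form is what this package computes, and reports should state
that definition when comparing against other software.

Both statistics are computed on person-level day-averaged contributions,
not pooled person-days: the screening question is about between-person
variation, and pooling days would mix within-person noise into it.

Coverage per nutrient is the sum of shares over foods assignable to an FFQ
item. The decision rule is inclusive at the threshold (both sums ≥ 80 % ⇒
sufficiently covered). For failing nutrients, unmapped foods with MOM1
and/or MOM2 ≥ 1 % become candidates, ordered by `max(MOM1, MOM2)`
descending with lexicographic food-code tie-breaks for determinism, and
the sums are recomputed with candidates treated as mapped — exactly
additive for MOM1 and for the candidates' own MOM2 shares. Output files
round percentages to one decimal; full precision is kept internally.

## Energy-intake plausibility

Implausibly low reported energy intake is screened with the per-individual
Goldberg form: exclude when EI/BMR < 0.87, keep at exactly 0.87 (the rule
targets reporters *below* the limit). BMR comes from the weight-only
Schofield regressions, `BMR = slope × weight + intercept` per sex × age
band, shipped as a configuration file (the schema permits adding a height
term). The full Goldberg formulation with physical-activity-level and
within-subject CV terms is out of scope; with a fixed 0.87 limit the screen
is conservative for a highly active population, which is the accepted
trade-off for individual-level screening.

## Diet-quality scoring

The index has 16 components, each 0–10, total 0–160. Component cut-offs
are data, not code: the packaged YAML reproduces the Dutch 2015 guideline
values (vegetables ≥ 200 g/d, fruit ≥ 200 g/d, wholegrain 90 g/d, nuts
15 g/d, dairy optimal 300–450 g/d, red meat full score ≤ 45 g/d and zero
at ≥ 100 g/d, and so on). Five scoring kinds cover all components:

| kind | shape | example |
|---|---|---|
| adequacy | `10·min(intake/threshold, 1)` | vegetables |
| moderation | 10 at ≤ lower, 0 at ≥ upper, linear between | red meat |
| optimum | 0 → plateau of 10 → 0 | dairy |
| ratio | `10·min(value/target, 1)` on soft:solid fat | fats and oils |
| binary | 10 iff intake ≤ cutoff | coffee (unfiltered) |

Scores are continuous (half points allowed); the total is the exact sum of
the 16 component scores. Degenerate-input conventions: a person reporting
no fats at all scores 10 on the fat-ratio component (no solid fat is full
compliance; the ratio is taken as infinite), and a wholly empty response
therefore scores 10 on every component whose optimum is zero intake
(alcohol, processed meat, …) and 0 elsewhere.

Micronutrient (vitamin B6, folate equivalents, B12, D, iron) and protein
scores are `10·min(intake/RDA, 1)` — the published description says only
that higher scores mean better compliance with the allowance, so the
linear capped rule is declared explicitly and both the RDAs and the rule's
inputs are configurable. The protein allowance is per kg body weight
(0.8 g/kg/d default), so body weight is a required input for it. These six
scores never enter the 0–160 total.

The packaged FFQ definition (40 questions, 55 items, item→component
weights, per-100 g densities) is a synthetic, schema-compatible inventory:
the production screener's item wording is proprietary. Eggs are
deliberately *not* an item — matching the screener under evaluation — but
the schema accepts added items, so the recommended future addition is a
config change, not a code change.

## Blood status and the advice engine

Panels are classified per analyte against sex-specific reference ranges
(haemoglobin and ferritin differ by sex; other analytes share one entry).
Boundary values classify as *within* — the inclusive convention, stated
here because laboratories differ. The shipped ranges file is explicitly
example data; real use requires the analysing laboratory's ranges.
Prevalence tables report counts and percentages on non-missing
denominators, overall and by sex.

Advice is generated by pure rules over (component scores, nutrient scores,
analyte status, diet type):

- component or nutrient score below the advice threshold (default 8/10,
  configurable — the production tool's cut-off is unpublished) ⇒ dietary
  advice item;
- analyte below range ⇒ blood-rule item; above range ⇒ a caution item with
  supplement-review wording (over-supplementation, notably vitamin B6, is
  the plausible cause when intake data cannot adjudicate);
- analyte below range *while* the corresponding dietary compliance score
  is at or above the threshold ⇒ the item becomes a cross-rule and the
  bundle's `further_diagnostics` flag is set: diet is unlikely to explain
  the deficit, so a physiological cause should be ruled out.

Vegetarians receive vegetarian template variants where defined;
flexitarians receive the omnivore wording. Templates are YAML data. Each
target (component, nutrient, analyte) carries at most one item, and the
engine is deterministic.

## Evaluation statistics

Normality is checked with a one-sample Kolmogorov–Smirnov test against a
normal with the sample mean and sd. Using estimated parameters without the
Lilliefors correction makes the test conservative; the method string in
the result records the choice. Totals are compared baseline vs follow-up
with a two-sided paired t-test; per-component changes use Wilcoxon
signed-rank tests with zero differences dropped before ranking (the
classic policy; recorded in the output attribute). All-zero-difference
components are skipped rather than tested. If everyone's total is
unchanged the t-test reports t = 0, p = 1; a constant nonzero shift (zero
variance of differences) is flagged degenerate instead, since the
statistic is undefined. No multiple-testing correction is applied across
the 16 components — each is reported at α = 0.05, and readers should treat
isolated component "significances" accordingly.

Satisfaction tables count answers per question with blank answers removed
from that question's denominator; percentages round to the nearest integer
with halves away from zero (20 of 29 → 69 %).

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage can be tested against known ground
truth.

**Recalls.** Person-level mean daily amounts per food are lognormal
(nonnegative, right-skewed — realistic for foods) with chosen
between-person sd; day-level amounts are normal around the person mean,
truncated at zero. Ground-truth level shares are density-weighted mean
amounts; ground-truth variance shares are `(density·between_sd)²`
normalised, exact under food independence when the within-person sd is 0
(day-averaging otherwise adds `within²/n_days` to each food's variance,
which the analytic truth ignores; the recovery tests therefore use zero
within-person noise, and correlated-food scenarios have only the
brute-force oracle, no closed form). The default 20-food profile set
targets a mean energy intake near 12.5 MJ/day — plausible for a training
population — and deliberately leaves eggs, shrimp and a sports drink
unmapped to the FFQ so that vitamin B12 and D coverage fails and the
candidate search finds real structure; shrimp gets a long-tailed
between-person distribution (an occasional extreme consumer). The
generator models honest reporting; the cohort driver scales 13 athletes'
amounts down to emulate the under-reporting the plausibility screen
exists to catch.

**FFQ responses.** For each component one driver item is set so that
adherence 1 reaches the full-score intake exactly (total 160 under the
default configuration) and adherence 0 the worst-scoring intake (total 0);
intermediate adherence draws a Beta-distributed per-person, per-component
interpolation. Sample sizes in the drivers mirror the screening setting:
48 athletes (29 men, 19 women) at baseline, 29 completers at follow-up.
Nutrient intakes implied by the drivers are conservative, so simulated
cohorts rarely reach compliance scores of 8+ and the cross-rule fires
mainly in designed test cases, not in the bulk simulation.

**Panels and paired scores.** Panel values are drawn by first sampling the
below/within/above category at the target prevalence, then placing the
concentration uniformly in the corresponding segment of the reference
interval; realised prevalence converges to the target. Paired totals add a
normal change (mean = designed shift, sd = designed spread) to normal
baselines, everything clipped to [0, 160].

All generators are seed-deterministic.

## Problem sizes and test design

The property tests run at sizes where their oracles are exact or tight:
brute-force covariance decompositions on ≤ 5-food instances, exhaustive
sign-enumeration Wilcoxon oracles on ≤ 8 pairs, and variance-share
recovery at n = 2000 persons with a ±2 percentage-point band (the
Monte-Carlo error of a two-food share at that n). The analysis drivers use
432 recall persons and 48/29 screening athletes, matching the cohort
structure the pipeline is designed for.

## Known limitations

- The covariance definition of the variance share is one of two published
  conventions; results are comparable only under the same definition.
- The fixed-cutoff Goldberg screen ignores activity level; for athletes it
  under-excludes rather than over-excludes.
- The FFQ definition, food profiles, reference ranges and advice wording
  are synthetic or example content — structurally faithful, numerically
  illustrative.
- Supplement intake is not modelled anywhere; above-range blood values can
  therefore only trigger review advice, not dose-based reasoning.
- Seasonality (relevant for vitamin D) and food–food correlation in real
  diets are not emulated by the default generators.
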