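---
title: "Diet-level nutrient profiling for older adults: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet-level nutrient profiling for older adults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnpsdiet)
```

## The problem

Nutrient profiling systems assign a quality score to a food from its
nutrients to encourage and to limit. Cohort studies, however, rarely record
foods; they record per-participant *daily intake estimates* from instruments
such as the brief diet-history questionnaire (BDHQ). Applying a food-based
system to such diet-level data raises two structural questions: should total
energy still be penalised (energy is necessary for life and is not scored by
diet-quality indices), and should the per-item credit caps — calibrated to
keep single foods from over-claiming — still truncate credit when the unit
of analysis is a whole diet? `mnpsdiet` implements a profiling system for
older adults in four variants that toggle exactly these two ingredients, and
the statistical machinery to compare them with established diet-quality
indices.

## The scoring model

Every variant scores nine encourage items and two or three limit items:

```{r}
load_profile_config("original")
```

* **Encourage credit**: `100 * min(intake/RDV, cap_fraction)` — linear in
  intake, saturating at the cap (the full RDV for the uncapped variants).
* **Limit deduction**: `100 * intake/RDV` — linear from zero and uncapped.

The per-item point formula is a package convention: the food-level system
this adapts publishes its reference daily values and caps but not a
diet-level point rule. The convention above is the simplest one consistent
with the "% of RDV" cap notation and with the percent-daily-value tradition
of the NRF family the system is compared against; it is held in the shipped
YAML profile (`inst/extdata/mnps_oa_profiles.yaml`) so that a different
published convention, or caps recalibrated to another population, can be
dropped in without code changes. Two further conventions matter:

* The energy deduction is proportional **from zero**, not excess-over-RDV.
  An excess-only rule would make the original and the without-energy-limit
  variants nearly identical for all realistic diets, erasing the contrast
  the variants exist to study.
* Totals are **not floored at zero**; rank-based validity analyses need the
  full range, and nothing in the system's definition truncates.
* Caps are stored as the printed absolute creditable amounts (calcium
  389.4 mg, fruits 113 g, vegetables 84.7 g, legumes 57 g, dairy 55 g)
  rather than recomputed from the rounded percentages — the absolute values
  carry more precision (note 57% of 200 g would be 114 g, not 113 g; the
  absolute value wins).
* Sodium is carried in **grams** end to end, the unit of its 7.5 g RDV;
  `read_diet_records()` takes a `sodium_unit = "mg"` schema flag so
  milligram sources cannot silently inflate deductions a thousandfold.

## Preprocessing

`apply_exclusions()` removes, in order, records without consent or checkup
attendance, then records with implausible energy (< 600 or > 4000 kcal/d,
strict inequalities — a record at exactly 600 kcal is kept). The ordering is
fixed so the bookkeeping of a two-stage exclusion is exactly reproducible.

The BDHQ cannot measure sugars, so `impute_sugars()` assigns them as
sex-specific percentages of energy (total 10.7%/13.5%, added 5.8%/7.2% for
men/women) converted to grams at the Atwater value of 4 kcal/g. The source
studies state only energy percentages; 4 kcal/g is the standard sugar energy
density and is an explicit argument should another convention be needed.
Scorers take sugar exclusively from this imputation — a record-level sugar
field is never consumed.

`to_density_profile()` applies the density method: macronutrients become a
percentage of energy via Atwater factors (protein and carbohydrate 4,
fat and saturated fat 9 kcal/g), everything else becomes amount per
1000 kcal. The profile is invariant to uniform scaling of energy and all
intakes, which the tests check directly. The sodium-to-potassium ratio is
computed mass-on-mass (mg/mg); the convention is fixed so correlations
against it are reproducible.

## Reference indices

**HEI-2015** (13 components, 9 adequacy + 4 moderation, 0–100) is scored on
densities with a shared linear ramp between each component's zero-score and
max-score standards. The shipped standards are the USDA 2015 component
standards with *approximate* gram-per-serving conversions (fruit 100 g and
vegetables/legumes 150 g per cup-equivalent, grains 28 g and protein foods
28.35 g per ounce-equivalent at 7 g protein per ounce, dairy 244 g per
cup-equivalent); the exact Japanese conversion tables used in prior work are
not public, so the conversion column is editable configuration. Two
data-availability conventions follow questionnaire practice: whole grains
can be forced to zero (`whole_grains_zero = TRUE`, the replication default
in `build_score_panel()`), and refined grains are read from an optional
column and treated as zero when absent, which scores that moderation
component at its maximum.

**NRF9.3** is the capped sum of percent daily values of nine encourage
nutrients minus the percent daily values of saturated fat, added sugars and
sodium. Daily values default to the profiling system's RDVs where the two
overlap (protein 60 g, fiber 20 g, calcium 750 mg, vitamin D 8.5 µg) and to
dietary-reference-intake style values elsewhere (vitamin A 900 µgRAE,
vitamin C 100 mg, iron 7.5 mg, potassium 3000 mg, magnesium 350 mg; limits
SFA 20 g, added sugars 50 g, sodium 7.5 g). The per-day basis with a 100%
cap on encourage items is the default; a per-100 kcal basis sits behind the
`basis` flag since both appear in the NRF literature.

**DQSJ** scores ten components 0–3 by sex-specific quartiles of
energy-adjusted intake (seven adequacy ascending, three moderation
descending), total 0–30. Quartile boundaries are *order statistics*
(inverse-ECDF quantiles) and ties fall to the lower stratum. This makes the
score a pure rank function, hence invariant to any strictly increasing
transform of a component's intakes — a property the test suite asserts — and
gives exactly uniform strata on continuous data when group sizes divide
by four. In replication mode, whole grains and nuts are fixed at 0 points
(non-consumption), capping the attainable total at 24.

## The synthetic cohort generator

`generate_cohort()` exists so every downstream stage is testable without
cohort access. Its design mirrors the measurement structure the analysis
assumes:

* Energy is lognormal (default median 1900 kcal, log-sd 0.20), drawn by
  rejection inside the 600–4000 kcal plausibility window; a specified number
  of records is then pushed outside the window, and another flagged
  non-consenting, so the eligibility filter has exact known answers.
* Nutrients and food groups are generated as lognormal **densities**
  (per 1000 kcal) coupled to energy through a Gaussian copula and then
  multiplied by energy. This induces the intake–energy confounding that
  motivates the density method (the tests verify that adjustment
  de-correlates intakes from energy), and, because Spearman correlation is
  copula-invariant, the specified coupling ρ implies a known population rank
  correlation, `6/π · asin(ρ/2)`, which the suite recovers within 3σ at
  n = 5000.
* Food groups add a point mass at zero for episodically consumed items
  (nuts, whole grains, sugar-sweetened beverages, fruits, dairy).

The default laws place median intakes near published national-survey levels
for Japanese adults aged 65+ (e.g. protein ≈ 38 g, calcium ≈ 300 mg,
potassium ≈ 1300 mg per 1000 kcal, sodium ≈ 2.4 g/1000 kcal so the Na/K
mass ratio sits near 1.9). They are plausibility settings chosen once and
documented — not estimates of any cohort's joint distribution. What the
generator does **not** emulate: questionnaire measurement error with
person-specific bias, intra-individual day-to-day variation, true food-group
co-consumption patterns, or seasonal effects. Passing tests therefore
demonstrate the *algorithmic* properties of the scorers and the *structural*
behaviour of the variant comparison (ordering of construct correlations,
direction of convergent-validity improvements, sign of the Na/K
association), not the numerical correlation values any real cohort would
produce.

## Numerical and degenerate-case choices

* Decile coarsening (the sensitivity analysis for differing score ranges)
  uses order-statistic cutpoints computed in integer arithmetic
  (`ceiling(n·k/10)`), avoiding floating-point wobble at exact decile
  boundaries; ties fall to the lower decile, matching the DQSJ convention.
* `spearman()` is Pearson correlation on average ranks; constant vectors are
  an error rather than `NA`, so silent degenerate correlations cannot enter
  a report. The independent cross-check in the tests is an exhaustive
  brute-force ranking oracle over all permutations up to length 8.
* Rank-sum descriptives use `stats::wilcox.test`, which enumerates exactly
  for small untied samples and applies the tie-corrected normal
  approximation otherwise; chi-square switches to Fisher's exact test when
  any expected cell is below 5. P-values are reported unadjusted, two-sided,
  with 0.05 as the conventional threshold.
* A zero-intake diet scores 0 in every variant; an all-identical DQSJ
  component places everyone in the lowest intake stratum.

## Problem sizes

The shipped tests exercise cohorts of 200–1130 records for behavioural
checks, 1102 post-exclusion records (two fixed seeds) for the
validity-pattern checks, and 5000 records for distributional recovery —
sizes at which the binomial and Fisher-z 3σ bands used in the assertions are
meaningfully narrow while the full suite runs in well under a minute of
compute per file.

## Known limitations

* The per-item point scale is a declared convention (see above); absolute
  score levels are therefore not comparable across software that chooses a
  different scale, though ranks — and everything the validity analysis
  uses — are insensitive to any common linear rescaling.
* HEI-2015 serving conversions are approximations; users replicating a
  specific national adaptation should supply their own standards table.
* The DQSJ quartile cutpoints are cohort-relative by definition: scores are
  not transportable across cohorts without re-deriving boundaries.
* Whether limit deductions should themselves be capped is not specified by
  the source system; they are uncapped here, which the variant-ordering
  invariants rely on.
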