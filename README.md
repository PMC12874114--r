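# mnpsdiet

Diet-level nutrient profiling for older adults, with validity analysis.

Nutrient profiling systems score the nutritional quality of *foods*, but the
dietary data available in most epidemiological cohorts are *diet-level*
estimates of daily intake from instruments such as the brief diet-history
questionnaire (BDHQ). `mnpsdiet` implements the diet-level adaptation of the
Meiji Nutritional Profiling System for Older Adults (MNPS-OA) in four model
variants, the comparison indices used to validate it (HEI-2015, NRF9.3 and
the Diet Quality Score for Japanese, DQSJ), the standard preprocessing for
questionnaire intakes, and a Spearman-based construct/convergent validity
analysis. A seeded synthetic cohort generator emulates BDHQ-like intake
structure so the whole pipeline is testable without access to any cohort
data.

It is intended for nutritional epidemiologists who want to apply or
recalibrate a food-based profiling system on diet-level data.

## The scoring model

For a daily diet with intakes \(x_i\), the MNPS-OA total is

    S = 100 * Σ_enc min(x_i / RDV_i, c_i)  −  100 * Σ_lim x_j / RDV_j

over nine items to encourage (protein 60 g, dietary fiber 20 g, vitamin D
8.5 µg, calcium 750 mg, fruits 200 g, vegetables 350 g, nuts 75 g, legumes
100 g, dairy 130 g) and up to three items to limit (energy 2400 kcal, sugar
60 g, sodium 7.5 g). Each encourage item credits points linearly up to its
*cap* \(c_i\), a fraction of the reference daily value (e.g. calcium credits
stop at 389.4 mg, 52% of the RDV). The four variants toggle the two
contested ingredients of a food-based system applied at diet level:

| variant    | energy limit | nutrient caps |
|------------|--------------|---------------|
| `original` | yes          | yes           |
| `wel`      | removed      | yes           |
| `wc`       | yes          | removed       |
| `wel_wc`   | removed      | removed       |

Sugar intake cannot be measured by the BDHQ and is imputed as a sex-specific
percentage of energy (total 10.7%/13.5%, added 5.8%/7.2% for men/women, at
4 kcal/g). Validity analysis uses Spearman rank correlations, with nutrient
intakes energy-adjusted by the density method (macronutrients as % of energy
via Atwater factors; micronutrients and food groups per 1000 kcal).

## Worked example

```r
library(mnpsdiet)

cohort <- generate_cohort(default_spec(1130, seed = 7,
                                       n_no_consent = 12L,
                                       n_energy_outliers = 16L))
kept  <- apply_exclusions(cohort)$kept          # 1102 eligible records
panel <- build_score_panel(kept)                # all seven scores
correlation_report(panel, to_density_profile(kept))
```

prints

```
Correlation report (n = 1102, mode = raw)

Construct validity (Spearman r with original model):
  variant       r_with_original
1 mnps_original           1
2 mnps_wel                0.946
3 mnps_wc                 0.608
4 mnps_wel_wc             0.490

Convergent validity:
  variant       hei2015 nrf9_3  dqsj
1 mnps_original   0.367  0.225 0.334
2 mnps_wel        0.389  0.396 0.378
3 mnps_wc         0.455  0.458 0.574
4 mnps_wel_wc     0.424  0.513 0.548
```

Removing the energy limit barely perturbs the ranking (construct r = 0.95
with the original model), while removing the nutrient caps changes it
substantially (r = 0.61/0.49) — and it is the uncapped variants whose
agreement with the established indices improves, across all three. That is
the qualitative signature the validity analysis looks for; the printed
numbers are for this synthetic cohort and will differ for real data.

`run_pipeline(out_dir, n = 1130, seed = 7)` performs the same analysis end
to end and writes the score table, descriptives, correlation reports and a
seeded run log to `out_dir`.

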