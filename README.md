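# fsdcase

Rule-based classification of **functional somatic disorder (FSD)** — the
EURONET-SOMA diagnostic proposal for persistent and troublesome physical
symptoms — from questionnaire cohort data, with the subgroup statistics and
penalized regression that go with it.

FSD requires at least one symptom that is *persistent* (at least six
months) and *troublesome* (moderately to severely impacting daily life);
cases are sub-classified by symptom pattern into **single-symptom**,
**single-system** and **multi-system** subgroups over the
cardiorespiratory, gastrointestinal, musculoskeletal, neurological/other
and fatigue-related symptom clusters. The package is written for
epidemiologists and methods researchers who want a tested, configurable
implementation of this operationalisation for population questionnaire
data — and a synthetic cohort generator with planted ground truth to
evaluate it against, since the population registers this kind of study
uses are access-restricted.

What it provides:

* **Symptom qualification** — one rule per source instrument: Widespread
  Pain Index (duration ≥ 6 months, hampers activities "quite a bit"+),
  ROME-III (duration > 6 months, frequency "often"+ on ≥ 3 days/month or
  hampering, per symptom), CDC Symptom Inventory ("a few times a week"+
  for > 6 months), Checklist Individual Strength (fatigue score ≥ 35 with
  a persistence flag), and SCL-90 somatization (moderate+ severity at two
  questionnaire waves). `extract_symptoms()` unions them.
* **Classification** — `classify_fsd()` applies the caseness and subgroup
  definitions; exhaustively verified against a brute-force oracle.
* **Optional specifiers** — same-system chronic disease, concurrent
  depression/anxiety, and configurable criteria sets for chronic fatigue
  syndrome, fibromyalgia and irritable bowel syndrome.
* **Subgroup statistics** — tie-corrected Kruskal–Wallis with
  ε² = H/(n−1), Dunn–Bonferroni post hoc pairs (0.05/6 ≈ 0.0083 for four
  groups), Pearson χ² with Cramér's V = √(χ²/(n·min(r−1,c−1))),
  interpretation labels, and small-cell masking.
* **Penalized regression** — elastic-net logistic regression for
  predictors of caseness (own coordinate-descent solver; 80/20 split,
  10-fold CV over (α, λ), the λ.1se rule, odds ratios, test-set AUC).
* **Synthetic cohorts** — `generate_cohort()` plants caseness, subgroup,
  symptom sets and syndrome flags, and emits questionnaire responses that
  the pipeline recovers exactly.

## Worked example

```r
library(fsdcase)

g  <- generate_cohort(generator_config(n = 5000), seed = 1)
sy <- extract_symptoms(g$cohort)
cl <- classify_fsd(sy, g$cohort$respondent_id)

mean(cl$is_case)
#> [1] 0.5966
table(cl$subgroup)
#>       non_case single_symptom  single_system   multi_system
#>           2017            919            546           1518
all(as.character(cl$subgroup) == as.character(g$truth$subgroup))
#> [1] TRUE
```

59.7% of this synthetic cohort meets the case definition (the generator
plants 58.6%), split roughly 31/18/51% across single-symptom,
single-system and multi-system — and the classification recovers the
generator's intended subgroup for every respondent, which is the
round-trip property the test suite enforces.

Subgroup comparison and effect sizes:

```r
dat  <- dplyr::left_join(g$cohort, cl, by = "respondent_id")
tabs <- compare_subgroups(dat, "subgroup",
                          continuous  = c("eq5d", "neuroticism"),
                          categorical = c("sex", "mini_anxiety"))
tabs$categorical[, c("variable", "statistic", "cramers_v", "label")]
#> # A tibble: 2 × 4
#>   variable     statistic cramers_v label
#>   <chr>            <dbl>     <dbl> <chr>
#> 1 sex               27.9    0.0748 negligible
#> 2 mini_anxiety      12.4    0.0498 negligible
```

Both effects sit below the small threshold here — the planted
associations act on caseness, not directly on the subgroup gradient, and
at n = 5000 that translates into Cramér's V under 0.1. The interpretation
conventions (small > 0.1, medium > 0.3, large > 0.5) are the ones used in
population studies of this design.

Penalized caseness model:

```r
design <- build_design_matrix(g$cohort, cl)
fit <- fit_fsd_model(design, alpha_grid = c(0, 0.5, 1), seed = 1)
fit
#> Penalized logistic caseness model
#>   alpha = 0.50, lambda = 0.01843 (lambda_1se), CV loss = deviance
#>   n = 4192 (train 3354 / test 838), test AUC = 0.596
#>   nonzero coefficients: 5 of 21
head(report_model(fit), 3)
#> # A tibble: 3 × 5
#>   feature           coefficient odds_ratio coefficient_display odds_ratio_display
#>   <chr>                   <dbl>      <dbl> <chr>               <chr>
#> 1 msk_condition           0.259       1.30 0.26                1.30
#> 2 providers_visited       0.196       1.22 0.20                1.22
#> 3 ldi                     0.177       1.19 0.18                1.19
```

The one-standard-error penalty keeps a handful of the planted predictors
(the musculoskeletal condition flag, healthcare visits, long-term
difficulties lead the table) and shrinks the noise covariates to ".",
with held-out AUC of 0.596 against the generator's Bayes-score AUC of
about 0.61.

## Documentation

The methods vignette (`vignettes/fsd-methods.Rmd`) describes the
diagnostic model, the per-instrument boundary conventions, the specifier
and syndrome configuration, the statistical conventions, the elastic-net
solver, and what the synthetic generator does and does not emulate.
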