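---
title: "Classifying functional somatic disorder from questionnaire cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional somatic disorder from questionnaire cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The diagnostic model

Functional somatic disorder (FSD) is a transdiagnostic proposal for
classifying persistent and troublesome physical symptoms across medical
specialties, without presupposing a somatic or psychological cause. The
case definition this package operationalises requires at least one symptom
that is both

* **persistent** — present for at least six months, and
* **troublesome** — moderately to severely impacting daily life,

as judged from the Likert responses of the instrument that measures the
symptom. Cases are sub-classified by symptom pattern into three diagnostic
subgroups: *single-symptom* (exactly one qualifying symptom),
*single-system* (two or more qualifying symptoms, all from one organ
system) and *multi-system* (qualifying symptoms from two or more organ
systems). The organ systems are cardiorespiratory, gastrointestinal,
musculoskeletal and neurological/other, plus a fatigue-related symptom
cluster discussed below.

Because the five source instruments encode duration, frequency and impact
differently, there is one qualification rule per instrument
(`qualify_wpi()`, `qualify_rome()`, `qualify_cdc()`,
`qualify_cis_fatigue()`, `qualify_scl()`):

| Instrument | Persistent | Troublesome |
|---|---|---|
| Widespread Pain Index (WPI) | duration six months **or longer** | hampers activities `quite_a_bit`+ |
| ROME-III | **longer than** six months | frequency `often`+ on ≥ 3 days/month, *or* hampers `quite_a_bit`+, per symptom |
| CDC Symptom Inventory | longer than six months | frequency `a_few_times_a_week`+ |
| Checklist Individual Strength (CIS) | six-month persistence flag | fatigue score ≥ 35 (the instrument's recommended cut-off, inclusive) |
| SCL-90 somatization | severity `moderately`+ at the second wave | severity `moderately`+ at the first wave |

Every rule emits a record with `persistent`, `troublesome` and
`qualifies = persistent & troublesome`; a missing response never reaches a
threshold. `extract_symptoms()` unions the rules, deduplicates by symptom
id (a symptom qualifying via two instruments counts once) and feeds
`classify_fsd()`.

### Boundary conventions

Duration is encoded as an ordered band
(`lt_3_months < 3_to_6_months < 6_months < more_than_6_months`) so the two
verbal conventions stay distinguishable and testable: "six months or
longer" is an inclusive comparison (`>= 6_months`, WPI), "longer than six
months" an exclusive one (`== more_than_6_months`, ROME and CDC). The CIS
cut-off of 35 is inclusive. These conventions are fixed in the rules and
exercised by exhaustive truth-table tests.

### The SCL two-wave convention

The somatization scale asks no duration question, so persistence is
operationalised as moderate-or-worse severity at *two* questionnaire
waves. We map *troublesome* to the first-wave severity and *persistent* to
the second-wave severity, which preserves the package-wide invariant
`qualifies == persistent & troublesome` while reproducing the intended
"moderate+ at both waves" semantics. The inter-wave gap (on average about
16 months in the kind of cohort emulated here) is reported descriptively
and not filtered on by default; an optional `scl_gap_window = c(min, max)`
filter is available for analyses that want to enforce a window.

### The ROME disjunct

Which troublesome route applies to each ROME symptom ("frequency" versus
"hampering") is symptom-specific configuration. Our defaults: stool-pattern
symptoms (loose bowel movements, hard stools, constipation) use the
frequency route; bloating, burning upper stomach and the meal-related
symptoms use the hamper route; abdominal pain accepts **either** route.
Abdominal pain is the one symptom for which both readings are defensible —
it is both a pain symptom (impact naturally measured by hampering) and the
anchor symptom of frequency-defined bowel disorders — so the permissive
disjunction is the default and both routes are tested.

### Fatigue as a fifth system

The four disease-bearing organ systems have no natural home for fatigue
and unrefreshing sleep. We keep `fatigue_related` as a fifth symptom
system by default — the diagnostic framework lists fatigue among its
symptom clusters — and `classify_fsd(fatigue_as_system = FALSE)` collapses
it into `neurological_other` for sensitivity analyses. The same-system
disease specifier never matches fatigue because no chronic-disease cluster
maps to it.

## Optional specifiers

`same_system_disease()` flags respondents whose qualifying symptoms and
self-reported chronic diseases share an organ system; diseases not clearly
attributable to one system (cancer, diabetes) are catalogued `unassigned`
and ignored. `syndrome_criteria()` evaluates three functional somatic
syndromes from declarative, fully configurable threshold sets that
approximate the CDC-1994 chronic fatigue syndrome definition (severe
persistent fatigue, CIS ≥ 45, plus at least two qualifying accompanying
symptoms), the ACR-2010/FSQ fibromyalgia definition (≥ 7 pain locations
with qualifying duration and impact) and ROME-III irritable bowel syndrome
(frequent persistent abdominal pain with a stool-pattern association
item). These defaults are the package's own documented operationalisation,
not a claim about any specific study's coding; the tests assert the
engine's agreement with an independent straight-line recoding of the same
configuration. A missing instrument bank yields `NA` ("undetermined"),
deliberately distinct from `FALSE`, so complete-case filters can act on
it.

## Subgroup statistics

Continuous variables are compared across the four subgroups with the
tie-corrected Kruskal–Wallis test; effect size is epsilon-squared,
$\epsilon^2 = H/(n-1)$, interpreted on the conventional ladder (negligible
≤ 0.01 < weak ≤ 0.04 < moderate ≤ 0.16 < relatively strong ≤ 0.36).
Pairwise contrasts use Dunn's procedure on the shared midranks with
Bonferroni control: four groups give $k(k-1)/2 = 6$ comparisons and a
per-pair threshold of $0.05/6 \approx 0.0083$. Categorical variables use
Pearson's chi-square (no continuity correction) with Cramér's
$V = \sqrt{\chi^2/(n\,\min(r-1, c-1))}$, interpreted as small > 0.1,
medium > 0.3, large > 0.5, with the exclusive-boundary convention (a value
of exactly 0.1 is below "small").

Three numerical conventions matter and are tested:

* p-values are asymptotic (chi-square); at the cohort sizes this package
  targets, exact tests are irrelevant;
* each analysis uses its **own** complete-case $n$ — effect sizes computed
  against the full cohort $n$ are visibly wrong whenever a variable has
  missing data;
* counts below 10 are masked as `"<10"` for display only
  (`mask_small_cells()`); analysis values are untouched.

## The penalized caseness model

Predictors of caseness are estimated by binary logistic regression with
the elastic-net penalty
$$\min_{\beta_0,\beta}\; -\tfrac{1}{n}\,\ell(\beta_0,\beta) +
\lambda\!\left[\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2 +
\alpha\lVert\beta\rVert_1\right],$$
solved by cyclic coordinate descent on the iteratively reweighted
least-squares approximation, with an active-set strategy and warm starts
along the penalty path. Convergence is declared on the
Karush–Kuhn–Tucker conditions (default tolerance `1e-8`; path fits use
`1e-7`), which makes the $\lambda = 0$ solution agree with a Newton–Raphson
maximum-likelihood fit to well below `1e-6`. The workflow
(`fit_fsd_model()`) is: complete-case filter, reproducible 80/20
train/test split, standardization of continuous predictors using
*training-set statistics only* (binary indicators stay on their 0/1
scale), 10-fold cross-validated selection of $(\alpha, \lambda)$, final
fit at the chosen penalty, and AUC (rank form, ties counted half) on the
held-out test set.

Two selection conventions are exposed because descriptions of this design
commonly mix them: the CV loss can be the binomial deviance (default) or
the Brier score ("mean squared error" of the predicted probability), and
the reported penalty can be `lambda_min` or the parsimonious `lambda_1se`
(default) — the largest penalty whose CV loss is within one standard error
of the minimum. The default alpha grid is $\{0, 0.25, 0.5, 0.75, 1\}$.

## The synthetic cohort generator

Population cohorts of the kind this pipeline targets are
access-restricted, so `generate_cohort()` provides the test bed. It is
two-stage: a latent stage draws demographics, covariates, caseness from a
planted logistic model, a diagnostic subgroup for each case, and an
intended symptom set consistent with that subgroup; an emission stage then
writes item responses so that every intended symptom passes its
qualification rule and every unintended response stays strictly below
threshold (with sub-threshold noise, so rules are exercised rather than
short-circuited). Classification therefore recovers the intended subgroup
*exactly*, which is what makes the round-trip acceptance test sharp.

The defaults are the emulated study conditions, fixed once: prevalence
0.586; subgroup mixture 31.3/17.7/51.9% of cases; system counts 2:3:4 in
proportion 32.7:15.6:2.6 among multi-system cases; planted odds ratios
1.78 (musculoskeletal condition), 1.57 (concurrent anxiety), 1.40
(gastrointestinal condition), 1.25 per SD (providers visited), 1.19
(neurological condition), 1.21 per SD (long-term difficulties), 0.79
(male), 1.06 per SD (loneliness); the caseness intercept is calibrated by
root-finding so the mean planted probability equals the target prevalence.
Demographic and covariate marginals (59% female, age ~ N(50, 13) clipped
to 18–95, 90% white European, Poisson counts for life events and
healthcare use, and so on) were chosen once as realistic for a northern
European population register and are documented in `generator_config()`.
The two SCL waves are separated by a Normal(16, 10)-month gap truncated at
one month, so ±10 months spans about one standard deviation. Syndromes are
planted only among cases whose intended symptom set makes the criteria
reachable (e.g. fibromyalgia only where widespread pain is intended), at
configured conditional rates; this keeps the round trip exact, at the cost
that overall syndrome frequencies sit below typical published population
rates — a deliberate trade of marginal realism for exact ground truth.

What the generator does *not* emulate: item-level measurement error or
response styles, within-person correlation between instruments beyond the
planted symptom structure, longitudinal drift beyond the two SCL waves,
and covariate-subgroup gradients other than those induced by the caseness
model. Passing tests therefore demonstrate the correctness of the rules,
classifier and estimators under clean planted structure — not the
field-data behaviour of the instruments themselves.

## Problem sizes and degenerate inputs

The test suite runs the exhaustive classifier check on all $2^6$ subsets
of six symptoms, full threshold grids per instrument rule, 50-dataset
oracle comparisons for the omnibus statistics, a 5,000-respondent
generator round trip, planted log-odds recovery at 20,000 respondents, and
20 repeated cross-validated lasso runs at $n = 2000$; the acceptance
script reuses the same sizes. Degenerate inputs have defined behaviour
throughout: identical values across all groups give $H = 0$; zero-margin
contingency tables are rejected naming the offending row or column; zero
cases produce empty distribution tables rather than division by zero;
empty instrument banks yield no symptom records; a missing syndrome bank
yields "undetermined", not "false"; complete separation at tiny penalties
is caught by bounded iterations with a warning.

## Known limitations

The symptom catalog ships a documented default assembled from the
instruments' published item sets; a study replicating a specific cohort's
coding should supply its own catalog, disease mapping and syndrome
criteria (all are plain configuration). Differential diagnosis — excluding
symptoms better explained by another medical condition — is out of scope,
as is multiple imputation: every analysis is complete-case and reports its
effective n. The package does not attempt to reproduce restricted-cohort
results (prevalence, omnibus statistics, fitted odds ratios, AUC) beyond
the structural and formula-level consistency checks described above.
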