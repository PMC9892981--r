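---
title: "Methods: MSA scoring, coaching assignment and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSA scoring, coaching assignment and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msacoach)
```

`msacoach` analyses a one-group pre/post digital-coaching trial in
metabolic syndrome. This vignette documents the models, the tunable
parameters, the numerical conventions, and what the synthetic data do and
do not establish.

## The MSA model and its staging

Metabolic Syndrome Age is a published sex-specific linear regression over
six predictors; the package treats the coefficient sets as configuration
data (`msa_coefficients()`, overridable from YAML via
`load_msa_coefficients()`) because they come from an external big-data
model that may be revised. Pulse pressure is SBP − DBP, the universal
clinical definition. Scoring is pure arithmetic with no internal rounding:
rounding happens only at the presentation layer, so staging never operates
on truncated values and linearity holds exactly (a +1 mg/dL change in HDL
moves the male score by exactly −0.481 years).

The MSA − CA difference is staged with a ±1-year band. Two conventions
needed fixing:

* **Orientation.** Descriptions of this staging in circulation are easy to
  garble; the unambiguous anchor is that *good* means metabolically
  younger. We stage *good* ⇔ diff < −1, *poor* ⇔ diff > +1. This is the
  only orientation consistent with a cohort whose mean difference is
  positive while the *poor* stage holds the largest share, and with
  coaching success meaning movement from *poor* toward *good*.
* **Band closure.** The band is closed at both ends (−1 and +1 are
  *average*), the simplest total partition of the line; the threshold is a
  parameter (`threshold`, years, default 1).

## MS criteria

Cutoffs are the harmonized criteria with Korean waist conventions
(WC 90/85 cm), shipped as `ms_thresholds()` defaults. Upper cutoffs are
inclusive on the abnormal side (≥) and lower cutoffs exclusive (<), the
guideline reading; a `strict = TRUE` switch gives literal strict
inequalities for sensitivity checks. Medication flags dominate measured
values, and lipid-lowering medication triggers *both* lipid criteria,
since the criterion wording attaches medication without distinguishing
drug class. Flags default to `FALSE` when a data file omits them, because
medication status is frequently uncollected in checkup-based cohorts.

## Coaching assignment

"Poorest indicator" is operationalized as the maximal direction-adjusted
z-score against sex/age-decade reference strata, restricted to indicators
whose MS criterion is met; HDL's z is sign-flipped so larger always means
worse. z-scoring is the minimal formalization of "compared with the same
sex and age group", and it is invariant to affine unit changes. Exact ties
break by the fixed priority obesity > blood_pressure > blood_sugar >
lipid, making assignment deterministic. The bundled reference table is
synthetic (plausible Korean-adult strata in 10-year bands, 20–29 … 70+);
real population statistics can be supplied as a CSV. The stage→step-target
policy (good 8000, average 9000, poor 10000 steps/day) is an explicit
package convention — deployed apps do not publish their mapping — and is a
plain named vector any caller can replace.

## Lifestyle metrics

Weekly ethanol grams follow freq × mL × vol% × 0.785/100, with 0.785 g/mL
the specific gravity of ethanol; content is entered as a percentage number
(4.5 for 4.5%). Sleep adequacy is the closed band [7, 8] hours versus
everything else. A "month" of step counts is a 30-day window anchored at
the participant's intervention start or end; days without records shrink
the denominator rather than counting as zero, because non-wear is not
inactivity, and an empty window yields `NA`, never 0.

## Pre/post statistics

Continuous variables get a paired t test (one-sample t on differences,
n − 1 df, two-sided). Nominal variables get the Pearson chi-square of
homogeneity on the 2 × k timepoint-by-category table with margin-derived
expected counts and df = k − 1 — the test such pre/post tables are
conventionally given even though timepoints are paired; the statistically
stricter McNemar test is exposed as `mcnemar_prepost()` for comparison.
No continuity correction by default (toggleable), no multiple-testing
correction. Degenerate inputs are handled explicitly: identical vectors
give statistic 0 and p = 1; a constant nonzero difference is flagged
`degenerate` with p = 0 rather than erroring; categories empty at both
timepoints are dropped from the test (they would zero an expected count)
but stay in the display. Expected counts below 5 in more than 20% of
cells attach a warning, and the test is still computed. The report
formats mean (SD) to 2 decimals, percentages to 1 decimal (half away
from zero), and p-values to 2 decimals with the leading zero dropped.
Analysis is complete-case on the pre/post pair; participants missing the
post visit are counted and excluded.

## The synthetic cohort generator

The generator's defaults encode the study conditions everything else is
tested under:

* **Marginals.** Each clinical indicator is a truncated normal with the
  trial's baseline mean/SD (height 164.80 (9.07), weight 66.86 (13.36),
  WC 79.65 (10.08), SBP 123.74 (11.53), DBP 75.39 (9.18), FBS 99.22
  (13.20), TG 129.68 (101.69), HDL 46.57 (19.02)); age is 47.61 (13.93)
  on [20, 80]. Truncation bias is removed at configuration time by
  numerically solving for the untruncated (μ, σ) whose truncated moments
  equal the targets (closed-form truncated-normal moments inside a
  Nelder–Mead solve, accepted only within 0.2% of the target mean and 1%
  of the target SD). TG's floor sits at the validation bound of
  20 mg/dL: its very large SD relative to its mean means no truncated
  normal with a higher floor can reach both moments (the SD ceiling at a
  floor of 30 is ≈ 99.7, below the target 101.69), so 20 is the least
  bound that matches the calibration exactly.
* **Dependence.** A Gaussian copula: a latent multivariate normal with
  mild positive correlations (0.15–0.5) among the adiposity, pressure,
  glycemia and lipid indicators and negative correlations with HDL
  (−0.15 to −0.45) is pushed through each marginal's quantile. The true
  correlations of such cohorts are unpublished; independence was
  rejected because it understates how often several criteria co-occur in
  one participant and hence the MS-group prevalence. Under these
  defaults a large generated cohort classifies to roughly 18/51/31%
  normal/risk/MS, bracketing the trial's 21/51/29%.
* **Sex and lifestyle.** The male share is the trial's 30/63 with a
  deterministic `round(n · p)` split (so n = 63 gives exactly 30:33);
  smoking 5/63, drinking 25/63, inadequate sleep 47/63 (75% short
  sleepers among them), diet good 35/63, stress a 1–5 discretized normal
  matching mean 3.04 (SD 0.91), exercise a rounded truncated normal
  4.11 (2.29), steps 6425 (3262) on [500, 30000]. Drinkers get 360 mL
  occasions at 4.5% vol — a beer-type convention; the trial reports its
  weekly-alcohol summary on a scale its own formula cannot produce, so
  no alcohol-grams target is calibrated.
* **Intervention effect.** Post = pre + printed mean delta +
  within-person noise (e.g. TG −20.49, steps +203), with noise drawn
  symmetrically truncated around zero inside each participant's headroom
  to the plausibility bounds so the conditional mean is preserved
  exactly wherever feasible. Participants whose shifted TG falls below
  the 20 mg/dL floor are clamped, compressing the recovered TG delta by
  roughly +1.6 in expectation — an unavoidable consequence of an
  additive shift meeting a hard floor, and the reason the delta-recovery
  test uses a 10% band. Category transitions use the printed turnover
  (1/5 smokers quit, 6/38 nondrinkers start, 10/47 sleepers reach the
  adequate band, 3/28 diets improve). Noise SDs are conventions chosen
  as plausible 3-month within-person variability; they are not
  calibrated to the trial's post SDs, which an additive model cannot
  reproduce anyway (the trial's TG SD *halves*, implying regression to
  the mean the additive model does not encode).
* **Attrition.** Stage-exact, non-informative removal:
  215 − 45 − 61 − 40 − 6 = 63, uniformly at random within stages.
  `generate_cohort()` keeps the pre-only rows of post-baseline dropouts
  on request, mirroring how a real analysis would log them.

**What passing tests show — and don't.** Moment recovery, dependence
directions, deterministic seeding, attrition conservation and the
group-mix bracket are properties of the generator, verified at n = 2×10⁴
to 10⁵. They show the pipeline behaves correctly on data *shaped like*
the trial's tables; they cannot validate the MSA model clinically, and
the synthetic stage distribution is notably flatter than the trial's
(the trial reports 48% of participants within ±1 year of their CA
despite an MSA−CA SD of 6.47 years, a concentration no smooth marginal
model reproduces — on synthetic data the ±1 band catches only a few
percent). The trial's p-values are not reproduction targets: its raw
data are unavailable and its contrasts were non-significant.

## Numerical conventions and degenerate inputs

* All randomness flows through one integer seed; pipeline stages derive
  fixed offsets from it. Identical (config, seed) gives byte-identical
  output files.
* Validation is total and categorized: schema errors name the missing
  column, duplicate (id, visit) records are their own error class, and
  invariant violations report row numbers. Plausibility bounds
  (height 100–220 cm, WC 40–200, SBP 70–250, DBP 40–150, FBS 40–500,
  TG 20–2000, HDL 10–150) are skippable with `relaxed = TRUE`; hard
  invariants (SBP > DBP, stress 1–5, sleep in (0, 24)) are not.
* A physiologic guard keeps generated DBP at least 2 mmHg below SBP;
  with the default correlation (0.7) the crossing probability is already
  below 10⁻⁸, so the guard does not disturb the calibrated moments.
* Problem sizes in the shipped tests: 10⁴ random inputs for the scoring
  oracle, 10³ random tables for the test oracles, 2×10⁴ for
  distributional checks, 10⁵ for the headline moment-recovery check;
  the full suite runs in well under a minute.

## Known limitations

* The synthetic cohort matches marginals and coarse dependence, not the
  joint distribution of a real checkup population; MSA−CA derived
  quantities (stage shares, mean difference) differ substantially from
  the trial's.
* The additive intervention model cannot shrink variances, so post SDs
  exceed the trial's for heavy-tailed indicators.
* The bundled reference strata are synthetic stand-ins; coaching-group
  proportions on synthetic data depend on them and carry no population
  meaning.
* The homogeneity chi-square ignores pairing by design fidelity; use
  `mcnemar_prepost()` when statistical correctness matters more than
  comparability.
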