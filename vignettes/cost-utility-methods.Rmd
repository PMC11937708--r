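---
title: "Methods: trial-based cost-utility analysis of an ePRO intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis of an ePRO intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprocua)
```

## The analysis

`eprocua` implements a trial-based stochastic cost-utility analysis (CUA)
of an electronic patient-reported outcome (ePRO) app evaluated alongside
two parallel two-arm RCTs: a breast-cancer trial during neoadjuvant
chemotherapy (`B_RCT`, 74/75 patients) and a prostate-cancer trial during
radiotherapy (`P_RCT`, 75/75). The perspective is the regional payer;
the horizon is the individual treatment period (under a year), so no
discounting is applied anywhere.

The chain is:

1. **Health outcome.** EORTC QLQ-C30 dimension scores, collected before
   and after treatment, are mapped to EQ-5D-3L response probabilities by a
   multinomial-logit response-mapping model and valued by a national value
   set, giving a predicted utility (EQ-5DP) per patient and time point.
2. **QALY loss.** Utility change is accrued linearly over the individual
   treatment duration $w_t$ (weeks):
   $\Delta\mathrm{QALY} = \frac{u_{\text{after}} - u_{\text{before}}}{2}
   \cdot \frac{w_t}{52}$. Negative values are QALYs lost.
3. **Costs.** Per-patient intervention cost is
   $C(w_t) = S/N + (\ell_n \cdot r/100)\,w_t + \ell_p\,w_t$ with startup
   cost $S$ = 5212 EUR amortized over the regional patient pool
   $N$ (518 breast / 683 prostate), nurse license $\ell_n$ = 39 EUR/week
   at $r$ = 5 nurses per 100 patients, and patient license
   $\ell_p$ = 2.25 EUR/week — an affine function with slope 4.2 EUR/week.
   Health-care costs arrive as per-contact amounts in 2019 SEK, are
   inflated within SEK (factor 1.0764) and then converted at the
   April-2022 rate (10.3257 SEK/EUR), in that order.
4. **ICERs.** Incremental cost over incremental QALYs
   (intervention minus control arm means) under three cost bases:
   *a* — intervention plus all health-care costs; *b* — intervention plus
   acute health-care costs; *c* — intervention costs only. Radiotherapy
   fractions are excluded from the prostate trial's health-care costs
   (treatment there is standardized, so between-arm RT differences are
   noise) and kept in the breast trial.
5. **Uncertainty.** A nonparametric bootstrap (default B = 1000) resamples
   patients with replacement within each arm at the original arm sizes,
   keeping each patient's cost and QALY values paired. Replicates feed the
   cost-effectiveness plane and the ICER summaries.
6. **Interpretation.** ICER point estimates are classified against the
   Swedish National Board of Health and Welfare cost-per-QALY bands:
   low (≤ 9685 EUR), moderate, high (> 48,423 EUR), very high
   (> 96,846 EUR); dominance labels short-circuit the bands.
7. **Exploration.** Acute-care ICD-10 codes are grouped into clinically
   similar categories, and per-patient utilization outcomes are regressed
   on arm, age, Charlson score, baseline EQ-5DP and (breast only) number
   of chemotherapy cycles, with the family chosen by overdispersion.

## Design choices where the design was open

Several points in the published procedure are under-specified; the package
fixes them as follows and exposes each as a parameter.

**Follow-up window.** "Six months" of utilization is implemented as the
half-open interval [0, 183) days from the first treatment day. Day offsets
are 0-based; an inpatient episode is a single event carrying its full
episode cost.

**Valuation rule.** "Mean predicted EQ-5D value" is read as an
expectation: EQ-5DP subtracts each dimension-level decrement weighted by
its response probability, and value-set extra terms (any-dysfunction and
any-level-3 constants) are weighted by their joint probability computed
under independence across dimensions — the only computable choice absent
joint coefficients. A modal rule (value the most-likely profile) is
available via `rule = "modal"`.

**Value sets.** A value set is an additive decrement table with an anchor
and optional extra terms, loaded from TSV. The British time-trade-off
tariff ships verbatim (`value_set_uk.tsv`; its worst-state value −0.594 is
the utility floor used throughout). The Swedish experience-based weights
are represented by a clearly labelled synthetic fixture
(`value_set_swedish_style_synthetic.tsv`) with the higher anchor and
milder decrements characteristic of experience-based tariffs; substitute
the published table for real analyses. Swapping value sets changes
utilities only, never response distributions.

**Mapping model.** Published QLQ-C30 → EQ-5D-3L mapping coefficients are
not redistributable here, so the package ships a synthetic coefficient
file with the identical multinomial-logit structure
(`mapping_model_synthetic.json`): per EQ-5D dimension, linear predictors
for levels 2 and 3 over selected QLQ-C30 scores, level 1 as reference.
Any coefficient file with that structure plugs in.

**ICER-c numerator.** The third variant's printed formula subtracts the
intervention group's intervention costs from themselves — an evident typo.
It is implemented as intervention-group intervention costs minus
control-group intervention costs, the latter identically zero (controls do
not use the app), matching the surrounding text.

**Confidence intervals.** The 95% CI is the 2.5th/97.5th percentile of the
replicate ICERs, the standard companion of a nonparametric bootstrap;
a normal-approximation interval (mean ± 1.96 SD) is available via
`ci = "normal"` for comparison with symmetric published intervals. Because
it is unclear whether published ICER means are means of replicate ICERs or
ratios of replicate means, `bootstrap_icer()` emits both (`icer_mean`,
`icer_of_means`).

**Near-zero denominators.** Bootstrap replicates with
|incremental QALY| < `epsilon` (default 1e-12) stay in the plane output
but are excluded from ICER mean/SD/CI, with the exclusion count reported;
unbounded ratios would otherwise destroy the summaries.

**Intervention prices.** License and startup prices are treated as already
denominated in 2022 EUR and bypass the inflation/exchange pipeline, which
applies only to SEK-denominated health-care costs. (At the stated mean
durations the cost equations evaluate below the published mean arm costs
of 92 and 43 EUR; the equations are taken as authoritative and evaluated
as printed.)

**ICD categorization.** Codes are normalized (uppercase, dots and
whitespace stripped — `R50.2` ≡ `R502`); dialect suffix letters
(`D709C`, `N390X`) match exactly as listed. A code belongs to at most one
category, first file row wins: `N390`, listed in the source both under
urinary tract infection and urinary problems, is kept in the former
(listed first). Prefix fallback matching is off by default. An acute event
whose codes hit two categories contributes its full cost to both —
categories are exploratory, not a partition.

**Overdispersion dispatch.** No numeric cutoff is published; the default
threshold is 1.5 on the Pearson $\chi^2/\mathrm{df}$ of a Poisson fit
(published goodness-of-fit values of 0.7–1.3 are consistent with it), and
it is configurable. Binary outcomes always use logistic regression. Cost
outcomes are rounded to whole EUR and modelled as counts by default
(matching the negative-binomial treatment of costs in the source), with a
gamma-log alternative via `family = "gamma"`. The negative-binomial
dispersion is estimated by maximum likelihood and CIs are Wald. The arm
variable is coded 0/1 with a per-model `reference` option, since published
tables flip the reference between analyses; flipping negates the group
coefficient exactly.

**Imputation.** Missing values are imputed as the mean per trial, arm and
time point (field), the single-imputation scheme of an ITT analysis under
a missing-completely-at-random assumption. Imputation precedes mapping:
QLQ dimension scores (or precomputed utilities) are completed first, then
mapped; per-patient aggregated cost fields are completed for patients with
administratively missing cost records. A warning fires when any cell
exceeds 10% missingness, the level above which simple imputation is
considered bias-prone. Imputation preserves each cell's observed mean
exactly.

## The synthetic cohort generator

No patient-level data from the source trials are public — utilization and
costs live in a regional administrative database — so the package carries
a generator whose defaults encode the two trials' published structure, and
every downstream stage is exercised against it.

Per trial and arm it draws: baseline EQ-5DP
(normal, truncated to [−0.594, 1]; defaults 0.86/0.87 breast, 0.88/0.89
prostate, SD 0.12/0.10), utility change (normal; defaults −0.02/−0.07
breast — the arm effect — and −0.01/−0.01 prostate, SDs 0.10/0.04),
treatment-plus-reporting weeks (normal, truncated at 1; mean 17 breast =
15 treatment + 2 reporting-tail weeks, SD 2; mean 8 prostate = 5 + 3, SD
0.5 — per-patient duration distributions are not published, so these are
chosen as realistic spreads around the published means), ages, Charlson
scores, and (breast) chemotherapy cycle counts. Care events are compound
Poisson: per-setting counts (defaults 35 outpatient / 1.5 inpatient per
breast patient, 8 / 0.2 prostate excluding RT), gamma per-event costs in
2019 SEK with shape/scale calibrated so EUR-2022 per-patient totals land
near the published arm means (e.g. breast outpatient: 35 × gamma(2,
scale 3800) SEK ≈ 27,700 EUR), per-setting acute probabilities (3%/35%
breast, 6%/80% prostate — acute care is a small share of outpatient cost
but a third to four-fifths of inpatient cost), ICD codes drawn from
per-trial pools mixing the named acute categories with routine treatment
codes, and, for the prostate trial only, five RT fractions per treatment
week flagged `is_rt_fraction`.

Two modes decouple mapping fidelity from CUA testing. `"direct"` attaches
the sampled utilities as precomputed EQ-5DP columns. `"item_level"`
realizes each sampled utility as a full QLQ-C30 profile: a severity
parameter s ∈ [0, 1] sweeps all dimensions from best to worst, the mapped
utility along that sweep is inverted by interpolation, and small
independent per-dimension jitter is kept only when the mapped utility
stays within 0.02 of the target. Near the mapping's ceiling (≈ 0.94 with
the synthetic model and British tariff) targets are attenuated — a real
ceiling effect of mapping algorithms worth knowing about when configuring
item-level simulations.

Missingness is injected separately ([inject_missingness()]) and is MCAR by
construction: per arm, `round(fraction × n)` patients are drawn without
replacement, so configured counts (e.g. 15 and 20 follow-up
questionnaires in the prostate arms, 2 cost records per intervention arm)
are hit exactly, and a log records who was blanked for verification.

What the generator does **not** emulate: survival/mortality and
informative dropout, within-patient correlation between utilization and
utility trajectories, seasonal or calendar structure in event timing, and
joint QLQ dimension correlation beyond the one-dimensional severity sweep.
Passing tests therefore show the pipeline's arithmetic and statistical
machinery is right under the stated data-generating assumptions — not that
those assumptions hold in any real cohort.

## Numerical notes

* Softmax probabilities are computed with a max-shift guard, so extreme
  linear predictors cannot overflow.
* Mean/SD summaries use the n − 1 denominator; a single observation
  reports SD as undefined (`NA`).
* The bootstrap resamples via index matrices and column means; with
  B = 1000 and 75 patients per arm a three-variant run takes well under a
  second.
* Quadrant labels on the plane send boundary points (a zero increment) to
  the north/east side, so tallies always sum to B.
* Cohort text files round-trip numeric fields exactly (full-precision
  serialization).

## Problem sizes used in the test suite

The suite validates the bootstrap against exhaustive enumeration of
within-arm resample multisets on cohorts of 2–3 patients per arm
(B = 10,000 against the exact mean), checks CI coverage of a known true
ICER on 100 seeded trial-sized cohorts (75 per arm, B = 1000), verifies
generator calibration at the published arm sizes, and runs the GLM
type-I-error study at 200 seeds × 500 patients. These sizes were chosen so
each property is tested at meaningful power while the whole suite stays
quick to run.

## Limitations

* The shipped mapping model and Swedish-style value set are synthetic
  stand-ins with the correct structure; headline utilities computed from
  them are not comparable to published values until real coefficient
  files are substituted.
* Published arm-level cost summaries cannot be reproduced without the
  administrative database; the package reproduces the published
  arithmetic (shares, equations, worked examples) and validates the rest
  by simulation.
* Group-mean imputation understates between-patient variance; with the
  published missingness fractions (up to 27%) the bootstrap intervals
  inherit that optimism, as flagged by the 10% warning.
* The utilization regressions are exploratory descriptors, not causal
  estimates; no zero-inflation or model averaging is attempted.
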