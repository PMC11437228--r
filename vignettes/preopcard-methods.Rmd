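---
title: "Methods: the preoperative cardiac risk algorithm and its matched-cohort evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the preoperative cardiac risk algorithm and its matched-cohort evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preopcard)
```

## The problem

Before elective surgery, clinicians must decide whether a patient needs a
cardiology consultation or cardiac testing. Done inconsistently, this
produces low-value referrals, surgical delays and cost. `preopcard`
implements a deterministic multi-step risk algorithm of the kind derived
from the ACC/AHA perioperative evaluation framework, and the retrospective
machinery to evaluate what happens to resource utilization and outcomes
when such an algorithm is rolled out: a two-period cohort comparison with
propensity-score matching, contingency analysis and E-value sensitivity
analysis, plus a seeded synthetic cohort generator so the whole pipeline is
testable without patient-level data.

## The decision algorithm

`aep_classify()` walks each record through ordered gates and stops at the
first that fires, yielding exactly one *algorithm end point* (AEP) per
patient:

1. **Active cardiac condition** → AEP 1, cardiology before surgery.
2. **Known cardiac disease with unclear status** → AEP 2, consider cardiology.
3. **Concern for myocardial ischemia** (nonacute symptoms) → AEP 3, consider cardiology.
4. **New or unevaluated abnormal ECG** → AEP 4, consider cardiology.
5. **Low-risk surgery** → AEP 5, proceed.
6. **RCRI score 0 and age < 65** → AEP 6, proceed.
7. **Modelled MACE risk < 1%** (MICA-style logistic, or an externally
   supplied NSQIP percentage) → AEP 7, proceed.
8. **Elevated risk but 4+ METS** → AEP 8, proceed.
9. **Elevated risk, < 4 METS, testing may change management** → AEP 9,
   consider cardiology.

A patient left after gate 9 (elevated risk, poor capacity, but testing
would not change management) proceeds to surgery; this fallthrough shares
end point 8 and is distinguishable in the decision trace. End points 1–4
and 9 constitute a *possible indication* for consultation; all others are
*no clear indication*.

Three design points were genuinely open and are decided here:

* **Order of gates 2–4.** The relative order of the unclear-status,
  ischemia and ECG gates cannot change the possible/no-clear dichotomy
  (any of them firing maps to a possible indication — the test suite
  proves this by enumeration), but for multi-flag patients it determines
  *which* of AEP 2/3/4 is recorded. The order above is fixed and
  documented rather than claimed clinically canonical.
* **End-point numbering.** Only the consult gates and the final gate have
  forced numbers; the proceed branches (5–8) are numbered in gate order.
  The numbering lives in one table (`aep_table()`) so renumbering cannot
  touch the logic.
* **Risk thresholds are strict** (`< 1%` risk, `< 4` METS, `< 65` years),
  matching their verbal definitions; the boundary values 1%, 4 METS and 65
  years therefore all fail their respective low-risk gates.

The MICA-style model is a configurable logistic,
`risk = 100·expit(β₀ + Σβᵢxᵢ)`; the package ships a clearly-labelled
*synthetic* coefficient file, and users supply transcribed published
coefficients to reproduce the real calculator. The RCRI is a six-component
count; the surgical-risk mapping is an explicit lookup table that errors on
unmapped procedures rather than guessing.

## Cohort construction

* **Exclusions.** Repeated `(patient_id, surgery_date)` rows keep the
  chronologically first visit; a record missing any of the four risk-tool
  fields (RCRI components, MICA percent, METS class, ASA class) is
  dropped. The accounting identity `final = screened − duplicates −
  missing` is asserted on every run.
* **Period assignment** is strict at the cutover: `pre` iff
  `visit_date < cutover` (default 2022-07-01); visits outside the two-year
  study window are flagged and excluded.
* **Service linkage (60-day window).** A consultation, echocardiogram,
  stress test or catheterization is preoperative iff
  `0 ≤ surgery − event ≤ 60` days — closed at both ends, so a
  same-day service counts. Event *completion* dates are used (services
  must have occurred). Repeated events collapse to one flag.
* **30-day outcomes.** An outcome counts iff `0 < event − surgery ≤ 30`
  days — the day of surgery itself is excluded, day 30 included. MACE is
  the set **union** of acute MI, revascularization, acute CHF and
  all-cause death, so the composite count is at most the sum of its
  components. The boundary conventions are a package decision (verbal
  window definitions rarely state them) and are fixed for determinism.

## Propensity matching

`fit_propensity()` is a logistic regression of post-period membership on
the baseline set (age, sex, race, ethnicity, six comorbidities, METS
class, ASA class, RCRI class, MICA class, surgical risk level). Scores at
the numerical boundary (≤1e−8 from 0 or 1) abort with a separation error
instead of silently producing degenerate matches.

`match_pairs()` is 1:1 greedy nearest-neighbour matching **on the logit**
of the score, without replacement, processing cases in a seeded random
order, with a caliper of 0.2 standard deviations of the logit. Source
material for such studies frequently leaves the matcher's order, caliper
and replacement policy unstated; these defaults are standard practice and
every one is a visible, logged argument. Distance ties break toward the
earlier-ingested control so runs are exactly reproducible. The matcher is
implemented over a sorted control array with union-find "nearest alive
neighbour" links, O(n log n), so study-scale cohorts (~25k records) match
in well under a second.

`balance_table()` reports the standardized mean difference *and* a
hypothesis test per covariate. SMDs are included deliberately: p-value
balance checks are sample-size dependent, so both views are emitted.

## Effects and sensitivity analysis

Pre-vs-post comparisons use the Pearson chi-square without continuity
correction; 2×2 tables with any expected cell below 5 fall back to the
Fisher exact test. Tables with more than two row classes and a significant
omnibus test get Bonferroni-adjusted pairwise post hoc comparisons —
never without the omnibus license. Age-style numeric comparisons use the
Mann-Whitney U test: the exact null distribution of U for small untied
samples (this reproduces full permutation enumeration), the tie-corrected
normal approximation otherwise.

The E-value for an observed odds ratio is

> E = RR + √(RR·(RR − 1)),

after converting OR to an approximate risk ratio: **directly** for a rare
outcome, by the **square-root rule** (RR ≈ √OR) for a common one, taking
the reciprocal first when RR < 1 (E-values are direction-invariant). The
common/rare switch is pooled prevalence ≥ 15% by default. Published
descriptions of the approach often omit the conversion rule; this pair of
conventions is the standard one, and it is the unique simple rule that
reproduces all four published E-values for the motivating study's
utilization table from its own printed counts (the acceptance suite checks
exactly that: 1.63, 2.14, 1.42, 1.65). The cutoff is configurable.

Report percentages use one decimal, rounding half away from zero
(`format_pct()`), matching clinical-table convention; empty denominators
give null percents, never 0.

## The synthetic cohort generator

`cohort_spec()` + `simulate_cohort()` draw a two-period clinic population
with:

* exact arm sizes (weighted sampling without replacement assigns periods),
* covariates sampled independently at configured prevalences — the
  defaults encode the matched-cohort marginals of the motivating study
  (e.g. CAD 10.4%, poor functional capacity ~14.6%, ASA 3–4 35%, ~36%
  any-cardiac-comorbidity burden),
* mild confounding: log-odds shifts (0.05–0.14) tilting sex, White race,
  atrial fibrillation, CAD, CKD, poor METS and high-risk surgery toward
  the pre period, the size of the imbalances such a study shows before
  matching,
* per-period service rates (consultation 23.2%/17.9%, echocardiogram
  6.9%/5.1%, …) and 30-day outcome rates at the study's levels, with
  event dates uniform inside the 60-/30-day windows and a small rate of
  decoy events outside them (which the linkage must ignore),
* age from a truncated normal (mean 63.5, SD 13.5, range 18–95), matching
  a median-64, IQR 53–72 population,
* optional planted duplicate visits and missing-score rows to exercise the
  exclusion funnel.

Covariates are generated **marginally**: only marginal prevalences are
available to emulate, so no dependence structure between comorbidities is
imposed, event timing is uniform for lack of any published timing
distribution, and the algorithm gate-flag prevalences (active cardiac
condition 0.5%, unclear status 2%, ischemia concern 2%, ECG flag 3%,
testing-would-change-management 50%) are order-of-magnitude choices, not
published margins. Consequently a passing pipeline on synthetic data shows
correctness of the *machinery* — windows, matching, tests, E-values,
classification — under realistic marginals and mild confounding; it does
not validate the algorithm clinically, nor reproduce joint-distribution
phenomena (comorbidity clustering, seasonal scheduling, site effects) of
real EMR data.

`inject_effect()` multiplies the post-period odds of one service, creating
a known ground-truth odds ratio for recovery experiments.

## Statistical operating characteristics

The acceptance suite measures, at sizes chosen to give stable Monte Carlo
estimates while keeping the default run fast:

* **Type-I error**: with no confounding and equal rates, the matched
  consultation comparison rejects at ≤ 2× nominal α = .05 over 200
  replicates of 2,000-patient cohorts.
* **Effect recovery**: an injected post/pre odds multiplier of 0.72 (true
  OR 1.39, the size of the motivating study's consultation contrast) is
  covered by the matched Wald 95% CI in ≥ 90% of 100 replicates.
* **Matched fraction**: on study-scale cohorts (~25.5k) with mild
  confounding, matching retains ≥ 90% of records across 20 seeds,
  consistent with the 91.4% retention the motivating study reports.
* **Greedy optimality**: for cohorts of ≤ 8 records the greedy total
  logit distance is within the documented worst-case greedy growth bound
  (≤ 3.5× exhaustive-optimal at this size; in practice it is almost
  always optimal).

## Known limitations

* The matcher is greedy; optimal/full matching and IPTW are out of scope.
* E-values are reported for the point estimate only, not the CI bound.
* The shipped surgical-risk map and MICA coefficients are illustrative /
  synthetic; institutional configuration is expected.
* The generator emulates marginals, not joint structure (above).
* Mortality here is whatever the events table says; no registry linkage.
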