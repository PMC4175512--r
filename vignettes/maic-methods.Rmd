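---
title: "Matching-adjusted indirect comparison of survival endpoints: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching-adjusted indirect comparison of survival endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maicsurv)
```

## Setting

Two randomized placebo-controlled trials study different active therapies in
the same disease — here emulating the advanced pancreatic neuroendocrine
tumor setting, in which an everolimus trial (individual patient data, IPD,
410 patients) and a sunitinib trial (published aggregates only, 171
patients) must be compared without head-to-head evidence. Both trials
allowed placebo patients to cross over to active therapy after progression,
which contaminates intention-to-treat overall survival (OS) and removes the
placebo arms as a common anchor for OS. This vignette describes the models
the package implements, the assumptions behind them, and the choices made
where published practice leaves the design open.

## The weight model

For IPD patient $i$ with matched covariate vector $x_i$ and a comparator
trial reporting target values $\bar{x}$ (proportions for binary or
categorical characteristics, medians for continuous ones), the MAIC weight
is $w_i = \exp(x_i^\top\beta)$, with $\beta$ minimizing the convex tilting
objective

$$Q(\beta) = \sum_i \exp\{(x_i - \bar{x})^\top \beta\}.$$

Since $\nabla Q(\beta) = \sum_i w_i (x_i - \bar{x})$, stationarity is
exactly the moment condition: every weighted mean equals its target. The
weights are proportional to each patient's odds of enrolment in the
comparator trial under a logistic enrolment model; the
method-of-moments form is the only estimable version when no comparator
IPD exists to fit that logistic regression directly.

Numerical choices:

* **Solver.** Newton iterations on the exact gradient and Hessian
  ($H = \sum_i w_i z_i z_i^\top$, $z_i = x_i - \bar{x}$), with step halving
  guarded by a relative objective tolerance of $10^{-9}$ — near the optimum
  the objective decrease falls below floating-point resolution, and an
  absolute-decrease line search would stall before the default balance
  tolerance of $10^{-10}$ (maximum absolute difference between weighted
  means and targets) is reached. In practice convergence lands at machine
  precision ($\sim 10^{-16}$).
* **Feasibility.** A target on or outside the observed range of its column
  admits no finite tilting coefficient (separation). This is detected
  before optimization and reported as infeasibility, distinct from a
  tolerance failure near the boundary.
* **Median matching.** A continuous characteristic with reported median $m$
  enters as the indicator $1\{x > m\}$ with target $0.5$; ties at the
  median count as below. Reports never state their tie convention, so this
  one is fixed and documented here; with continuous covariates it is
  immaterial.
* **Categorical characteristics** with $k$ reported levels enter as $k-1$
  indicators, the omitted level serving as reference.
* **Weight scale.** Weights are used raw for estimation (all weighted
  estimators are invariant to a common rescaling) and normalized to sum to
  the effective sample size $\mathrm{ESS} = (\sum w)^2/\sum w^2$ for
  display.

Eligibility is harmonized before weighting: WHO/ECOG performance status 2
patients are removed (the comparator trial excluded them by design), and
complete-case removal handles missing matched covariates, mirroring the
published accounting of 410 − 15 − 1 = 394.

## Weighted survival estimation

All comparisons run through weighted Kaplan–Meier curves and a weighted Cox
proportional-hazards partial likelihood for a single group indicator:

* **Ties** use the Efron convention — the trials' reports do not state a tie
  convention, and Efron is the more accurate default.
* **Variance** is the weight-robust sandwich estimator treating weights as
  fixed, the standard practice for matching-adjusted weights; the reports
  give confidence intervals but not their variance estimator. With uniform
  weights and balanced groups the sandwich agrees with the model-based
  variance to within 1% on the package's fixtures.
* **p-values** are two-sided Wald tests on the log scale, consistent with
  the interval construction. The normal quantile is carried as 1.959964
  for determinism; printed intervals round identically either way.

## Pseudo-IPD reconstruction

Comparator outcomes exist only as published curves. The reconstruction
inverts the product-limit estimator given a digitized curve and the
numbers-at-risk row: within each interval between consecutive at-risk ticks,
integer event and censoring counts are allocated so the recomputed
Kaplan–Meier estimate reproduces the digitized drops and hits the published
count at the next tick, iterating on the interval's censor count until the
risk sets match.

* **Interval convention.** A drop digitized exactly at an at-risk tick is
  allocated to the interval the tick closes: the published count at the
  tick already excludes those events. (Equivalently, interval $i$ owns the
  digitized points with times in $(t_i, t_{i+1}]$.) With grid-aligned
  digitization this convention makes the round trip exact up to integer
  rounding; assigning boundary drops to the following interval
  double-counts them against the anchor.
* **Censoring placement** is uniform within intervals, the dominant
  published convention; events sit exactly at the digitized drop times,
  preserving the visual steps.
* **Final interval.** Beyond the last tick no anchor exists; censoring is
  taken as zero unless a published total event count pins it down, in which
  case the final censor count is searched to honor the total.
* **Verification.** Each reconstruction recomputes its curve (default
  tolerance 0.5 survival percentage points; integer allocation contributes
  about $1/n$ per event, so small arms warrant a looser setting) and, when
  a paired arm exists, the hazard ratio against the published value
  (default 10% relative). Inputs implying more events than the at-risk
  counts permit are rejected with the offending interval named.

## The four comparisons

* **Anchored (Bucher) PFS.** $\log \mathrm{HR}_{AC} = \log \mathrm{HR}_{AB}
  - \log \mathrm{HR}_{CB}$ with summed variances; the IPD-side effect is the
  weighted Cox fit, the comparator side the published effect with its
  log-scale standard error back-calculated as
  $(\ln u - \ln\ell)/(2 \times 1.959964)$. Anchoring preserves
  randomization within both trials. PFS is usable because progression
  precedes crossover.
* **Unanchored active vs active (OS, PFS).** The weighted IPD active arm is
  pooled with the reconstructed comparator active arm. Before pooling, the
  IPD weights are normalized to sum to their effective sample size: in a
  pooled fit only the scale of one arm's weights *relative to the other
  arm's unit weights* matters, so the arbitrary scale of the estimated
  weights would otherwise leak into the estimate. The ESS scale removes it
  and lets the weighted arm carry exactly its information content. Validity
  requires all prognostic cross-trial differences to be balanced — a
  stronger assumption than anchoring needs.
* **External control (OS).** The comparator's placebo arm (whose patients
  could cross over to its active therapy after progression) serves as an
  external control for the weighted IPD active arm; numbers needed to treat
  are the reciprocal 12- and 24-month survival differences, reported to one
  decimal and never rounded to an integer, with negative differences
  flagged as number needed to harm.
* **Negative control.** Placebo-arm PFS across trials: unaffected by
  crossover, so any hazard ratio away from 1 estimates the direction and
  magnitude of residual imbalance from characteristics the matching could
  not see.

Adverse events are compared as the ratio of within-trial odds ratios
(active vs placebo in each trial), which cancels trial-level differences in
ascertainment. IPD counts are censored at the comparator arms' maximum
follow-up first. Weighted 2×2 cells are converted to effective counts on
the ESS scale before the Woolf variance $\sum 1/\text{cell}$ is taken —
raw weighted counts would be anti-conservative. Zero cells receive the
classical 0.5 correction on all four cells of the affected table, flagged;
events at or below the 5% reporting threshold in both comparator arms are
flagged non-comparable. No multiplicity adjustment is applied by default,
matching the exploratory character of cross-trial adverse-event screens;
Bonferroni and Benjamini–Hochberg corrections are available behind a flag.

## The synthetic two-trial generator

Because the IPD of the emulated trial is proprietary and the comparator
exists only in print, the package ships a generator whose defaults *are*
the study conditions, and every downstream stage is validated against it:

* Baseline covariates are drawn independently at the reported margins
  (performance status 0 at 68.8% vs 55.0%, prior somatostatin analogues
  49.2% vs 36.3%, prior chemotherapy 48.7% vs 69.0%, and so on); age is a
  shifted gamma calibrated so its *median* equals the reported median,
  since medians are what the matching uses. Reports publish only
  marginals, so no correlation structure is imposed.
* Progression and death are exponential given covariates — the simplest
  law satisfying proportional hazards, sufficient for parameter-recovery
  testing. PFS is the minimum of the two latent times. Placebo medians sit
  at the reported 4.6 and 5.5 months; conditional treatment effects at the
  reported within-trial PFS hazard ratios (0.35, 0.42).
* Crossover happens exactly at progression for a Bernoulli-selected 73%
  (IPD trial) or 69% (comparator) of placebo progressors, after which the
  death hazard is multiplied by a configured factor (default 0.60) — a
  piecewise-constant switch, the minimal mechanism that attenuates the
  intention-to-treat OS contrast toward 1, which the tests verify by
  paired simulation.
* Administrative censoring at 39 and 30 months reflects the different data
  cutoffs.
* The two trials differed in imaging schedules (12-weekly vs week 5, 9 and
  8-weekly); no published quantity calibrates the induced
  assessment-time bias, so the generator exposes an optional
  assessment-grid rounding of progression times that is off by default.

What passing tests do *not* show about real data: the generator has
independent covariates, exponential hazards, perfectly specified margins
and no measurement error in digitization beyond grid rounding. Real
applications face correlated covariates, non-proportional hazards,
digitization noise and — crucially — unmeasured cross-trial differences
that no weighting can fix; the negative control estimates, but cannot
remove, that residual confounding.

## Problem sizes used in validation

The test suite exercises the estimators at the scale of the emulated
analysis: weight fitting and balance at n = 394 after eligibility;
confidence-interval coverage over 200 simulated trials of 394 patients;
the confounding-correction property over 500 paired replicates of two
150-per-arm trials; the digitization round trip at 200 patients per arm on
a 1-month grid with at-risk counts every 8 months. Null calibration
(log-rank uniformity, zero-centered log hazard ratios) uses smaller trials
over a few hundred replicates.

## Known limitations

* Weighting can only balance characteristics reported by both trials;
  everything else lands in the negative control.
* The unanchored comparisons abandon randomization entirely; they are
  adjusted historical-control comparisons and inherit the limitations of
  observational evidence.
* The back-calculated standard error of a published effect assumes the
  interval was Wald-type on the log scale.
* Reconstruction fidelity is limited by the digitization grid and integer
  allocation (roughly one event's worth of survival, $1/n$, per step).
* The effective sample size describes precision loss from weighting, not
  bias; a small ESS signals fragile extrapolation toward the comparator
  population.
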