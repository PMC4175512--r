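# maicsurv

Matching-adjusted indirect comparison (MAIC) of survival endpoints between a
trial with individual patient data (IPD) and a trial available only as a
published report.

## The problem

When two treatments have each been compared to placebo in separate randomized
trials but never head to head, their relative efficacy must be estimated
indirectly. Two obstacles are common in oncology:

1. **Cross-trial population differences.** Baseline characteristics
   (performance status, prior therapy, disease burden) differ between trial
   populations and can confound a naive comparison of published hazard
   ratios.
2. **Crossover contamination.** Control-arm patients who progress are
   typically allowed to cross over to active therapy, so intention-to-treat
   overall survival (OS) no longer measures drug-versus-placebo efficacy and
   the placebo arms of the two trials are no longer a common anchor.

The motivating application is advanced pancreatic neuroendocrine tumors,
where everolimus and sunitinib were each approved on placebo-controlled
trials with post-progression crossover and no head-to-head evidence exists.

## The method

With IPD from one trial and published aggregates from the other, each IPD
patient receives a weight

```
w_i = exp(x_i' beta)
```

where `x_i` holds the matched baseline characteristics (binary indicators
and `1{value > reported median}` indicators for continuous variables). The
coefficients solve the convex program

```
minimize  sum_i exp((x_i - x_target)' beta)
```

whose first-order condition forces every weighted mean to equal its reported
target *exactly* (method-of-moments exponential tilting — the weights are
proportional to each patient's odds of enrolment in the comparator trial
under a logistic enrolment model). Precision loss is summarized by the
effective sample size `ESS = (sum w)^2 / sum w^2`.

On the weighted sample the package assembles:

* **Anchored (Bucher) comparison** of progression-free survival (PFS):
  `log HR_AC = log HR_AB - log HR_CB`, variances summed, using the weighted
  Cox HR for the IPD trial and the published HR + CI for the comparator.
* **Unanchored active-vs-active comparisons** of OS and PFS, pooling the
  weighted IPD active arm with comparator-arm pseudo-IPD reconstructed from
  the digitized Kaplan-Meier curve and numbers at risk.
* **External-control comparison** of the IPD active arm against the
  comparator trial's placebo arm, with numbers needed to treat
  `NNT = 1 / (S_active(h) - S_control(h))` at 12 and 24 months.
* **Negative control**: placebo-arm PFS compared across trials. PFS is not
  affected by post-progression crossover, so a hazard ratio away from 1
  measures residual cross-trial imbalance.
* **Placebo-adjusted adverse-event odds ratios** with follow-up
  harmonization and Woolf-type variances.

All weighted survival estimation runs through weighted Kaplan-Meier and
weighted Cox partial likelihood (Efron ties) with a weight-robust sandwich
variance. A synthetic two-trial generator with covariate-dependent
proportional hazards and progression-triggered crossover makes every
pipeline stage testable without any proprietary data.

## Worked example

```r
library(maicsurv)

cfg <- example_analysis_config(seed = 101)  # paired synthetic trials
res <- run_analysis(cfg)
print(res)
```

```
Matching-adjusted indirect comparison analysis
  retained 396 patients (excluded: ecog 14, missing 0); ESS 275.0

Comparisons:
                                        comparison endpoint              kind
 active vs comparator-active (anchored, pre-match)      pfs          anchored
            active vs comparator-active (anchored)      pfs          anchored
          active vs comparator-active (unanchored)       os unanchored_active
          active vs comparator-active (unanchored)      pfs unanchored_active
                        active vs external control       os  external_control
  placebo vs comparator-placebo (negative control)      pfs  negative_control
   hr ci_lower ci_upper p_value
 1.00     0.68     1.47  0.9990
 1.05     0.71     1.55  0.8200
 1.09     0.76     1.56  0.6430
 1.27     0.97     1.66  0.0833
 0.94     0.66     1.34  0.7240
 1.27     0.98     1.65  0.0663

NNT at 12 months: 48.3  [S_active = 0.66, S_control = 0.64]
NNT at 24 months: 40.8  [S_active = 0.48, S_control = 0.45]
```

Reading the output: 14 of 410 simulated patients were removed to harmonize
eligibility (performance status 2 is not eligible in the comparator trial);
reweighting the remaining 396 to the comparator's reported margins costs
precision (effective sample size 275). Each comparison row is a hazard ratio
with its 95% interval; the two active therapies look similar on every
endpoint in this replicate, the negative-control hazard ratio of 1.27
(CI 0.98-1.65) quantifies residual placebo-arm PFS imbalance, and the small
survival differences against the external control at 12 and 24 months
translate into large numbers needed to treat.

The weight model itself is a first-class fitted object:

```r
fit <- res$weights        # class "maic"
summary(fit)              # coefficients and the balance table
plot(fit)                 # pre/post-match balance chart
weights(fit, "ess")       # display-scale weights
```

After matching, every weighted mean equals its target (balance error
< 1e-10 above); the enrolment-model coefficients show which characteristics
drive the reweighting.

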