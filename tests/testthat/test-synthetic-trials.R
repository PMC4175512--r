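test_that("rejects degenerate configurations", {
  expect_error(trial_config(100, baseline_hazard_pfs = 0), "finite and > 0")
  expect_error(trial_config(100, baseline_hazard_os = Inf), "finite and > 0")
  expect_error(trial_config(100, covariate_margins = list(ecog0 = 1.2)),
               "\\[0, 1\\]")
  expect_error(trial_config(0), "n_per_arm")
})

test_that("covariate margins are recovered at the configured targets", {
  cfg <- trial_config(
    n_per_arm = 197, seed = 31,
    covariate_margins = list(age_median = 58, ecog0 = 0.688, prior_ssa = 0.492,
                             prior_chemo = 0.487, sites1 = 0.282,
                             sites2 = 0.368, distant_mets = 0.962))
  rec <- simulate_trial(cfg)
  n <- nrow(rec)
  expect_equal(n, 394)
  check <- c(ecog0 = 0.688, prior_ssa = 0.492, prior_chemo = 0.487,
             sites3 = 1 - 0.282 - 0.368, distant_mets = 0.962)
  for (nm in names(check)) {
    p <- check[[nm]]
    expect_lt(abs(mean(covariate_feature(rec, nm)) - p),
              3 * sqrt(p * (1 - p) / n))
  }
  # shifted-gamma age is calibrated on the median
  expect_lt(abs(median(rec$age) - 58), 2)
})

test_that("null configuration gives exchangeable arms", {
  ps <- vapply(1:150, function(r) {
    d <- simulate_trial(trial_config(n_per_arm = 40, seed = r,
                                     baseline_hazard_pfs = 0.1,
                                     censor_cutoff_months = 30))
    chi <- survival::survdiff(survival::Surv(pfs_time, pfs_event) ~ arm,
                              data = d)$chisq
    1 - stats::pchisq(chi, 1)
  }, numeric(1))
  # log-rank p-values uniform: rejection rate at its nominal level
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 150))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("null configuration log hazard ratio is centered at zero", {
  est <- vapply(1:300, function(r) {
    d <- simulate_trial(trial_config(n_per_arm = 60, seed = r,
                                     baseline_hazard_pfs = 0.1,
                                     censor_cutoff_months = 30))
    unname(stats::coef(survival::coxph(
      survival::Surv(pfs_time, pfs_event) ~ I(arm == "active"), data = d)))
  }, numeric(1))
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
})

test_that("crossover selects the configured fraction of placebo progressors, at progression", {
  cfg <- trial_config(n_per_arm = 400, seed = 9, crossover_probability = 0.73,
                      baseline_hazard_pfs = 0.15, baseline_hazard_os = 0.03,
                      post_crossover_log_hr_os = log(0.6),
                      censor_cutoff_months = 60)
  rec <- simulate_trial(cfg)
  plc <- rec[rec$arm == "placebo", ]
  progressed <- plc$pfs_event & plc$pfs_time < plc$os_time
  frac <- mean(!is.na(plc$crossover_time[progressed]))
  expect_lt(abs(frac - 0.73), 3 * sqrt(0.73 * 0.27 / sum(progressed)))
  crossed <- !is.na(plc$crossover_time)
  expect_equal(plc$crossover_time[crossed], plc$pfs_time[crossed])
  expect_true(all(rec$crossover_time >= rec$pfs_time, na.rm = TRUE))
  expect_true(all(rec$pfs_time <= rec$os_time + 1e-12))
  expect_true(all(is.na(rec$crossover_time[rec$arm == "active"])))
})

test_that("crossover attenuates the intention-to-treat OS hazard ratio", {
  itt_loghr <- function(crossover, r) {
    cfg <- trial_config(n_per_arm = 200, seed = r,
                        baseline_hazard_pfs = 0.12, baseline_hazard_os = 0.04,
                        log_hr_treatment_os = log(0.6),
                        crossover_probability = crossover,
                        post_crossover_log_hr_os = log(0.5),
                        censor_cutoff_months = 36)
    d <- simulate_trial(cfg)
    unname(stats::coef(survival::coxph(
      survival::Surv(os_time, os_event) ~ I(arm == "active"), data = d)))
  }
  pairs <- vapply(1:30, function(r) c(itt_loghr(0.73, r), itt_loghr(0, r)),
                  numeric(2))
  # contaminated estimates sit closer to 0 than the clean ones
  expect_gt(mean(pairs[1, ]) - mean(pairs[2, ]), 0.1)
  expect_gt(mean(pairs[1, ]), mean(pairs[2, ]))
})

test_that("same seed and config give byte-identical output", {
  cfg <- example_ipd_config(seed = 77)
  expect_identical(simulate_trial(cfg), simulate_trial(cfg))
})

test_that("aggregate summary exposes the published view consistently", {
  cfg <- trial_config(n_per_arm = 200, seed = 13, baseline_hazard_pfs = 0.1,
                      baseline_hazard_os = 0.05, log_hr_treatment_os = log(0.6),
                      censor_cutoff_months = 40)
  rec <- simulate_trial(cfg)
  agg <- summarize_as_aggregate(rec, grid_step = 1, at_risk_step = 8)
  for (key in names(agg$at_risk))
    expect_equal(agg$at_risk[[key]]$n_risk[1], 200)
  for (key in names(agg$km_curves)) {
    cv <- agg$km_curves[[key]]
    expect_equal(cv$survival[1], 1)
    expect_true(all(diff(cv$survival) <= 1e-12))
  }
  expect_true(agg$published_hr$os$ci_lower < agg$published_hr$os$hr)
  expect_error(summarize_as_aggregate(rec[rec$arm == "active", ], cfg),
               "empty arm")

  # degenerate case: no events at all leaves every curve at 1
  flat <- simulate_trial(trial_config(n_per_arm = 30, seed = 2,
                                      baseline_hazard_pfs = 1e-8,
                                      baseline_hazard_os = 1e-8,
                                      censor_cutoff_months = 12))
  agg0 <- summarize_as_aggregate(flat, grid_step = 2, at_risk_step = 6)
  for (key in names(agg0$km_curves))
    expect_true(all(agg0$km_curves[[key]]$survival == 1))
})
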