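test_that("log-scale standard errors are backed out of published intervals", {
  expect_equal(se_from_ci(published_effect(0.38, 0.29, 0.49)), 0.13381,
               tolerance = 1e-4)
  expect_equal(se_from_ci(published_effect(0.42, 0.26, 0.66)), 0.23765,
               tolerance = 1e-4)
  expect_equal(se_from_ci(published_effect(1.0, 0.5, 2.0)), log(4) / 3.919928,
               tolerance = 1e-6)
  expect_error(published_effect(0.5, -0.1, 1), "0 < ci_lower")
  expect_error(published_effect(0.5, 0.6, 1), "ci_lower <= hr")
})

test_that("the anchored combination reproduces the printed contrast", {
  ab <- published_effect(0.38, 0.29, 0.49, endpoint = "pfs")
  cb <- published_effect(0.42, 0.26, 0.66, endpoint = "pfs")
  res <- bucher(ab, cb)
  expect_equal(res$effect, 0.38 / 0.42, tolerance = 1e-10)
  expect_equal(round(res$effect, 2), 0.90)
  expect_equal(round(res$ci_lower, 2), 0.53)
  expect_equal(res$kind, "anchored")

  # the matched-scenario inputs divide to 0.83 from the printed values
  res2 <- bucher(published_effect(0.35, 0.24, 0.52, endpoint = "pfs"), cb)
  expect_equal(res2$effect, 0.35 / 0.42, tolerance = 1e-10)

  same <- bucher(ab, ab)
  expect_equal(same$effect, 1)
  expect_equal(same$p_value, 1)

  expect_error(bucher(ab, published_effect(0.5, 0.3, 0.8, endpoint = "os")),
               "endpoint mismatch")
})

test_that("swapping the anchored arms gives the exact reciprocal", {
  ab <- published_effect(0.38, 0.29, 0.49, endpoint = "pfs")
  cb <- published_effect(0.42, 0.26, 0.66, endpoint = "pfs")
  f <- bucher(ab, cb)
  r <- bucher(cb, ab)
  expect_equal(f$effect, 1 / r$effect, tolerance = 1e-12)
  expect_equal(f$p_value, r$p_value, tolerance = 1e-12)
  expect_equal(f$ci_lower, 1 / r$ci_upper, tolerance = 1e-12)
})

test_that("numbers needed to treat follow the reciprocal survival difference", {
  act <- km_steps(c(6, 18), c(0.82, 0.65))
  ctl <- km_steps(c(6, 18), c(0.70, 0.54))
  n12 <- nnt_at(act, ctl, 12)
  expect_equal(n12$surv_active, 0.82)
  expect_equal(n12$surv_control, 0.70)
  expect_equal(round(n12$nnt, 1), 8.3)
  n24 <- nnt_at(act, ctl, 24)
  expect_equal(round(n24$nnt, 1), 9.1)
  expect_true(n24$extrapolated)

  tie <- nnt_at(act, act, 12)
  expect_true(tie$infinite)
  expect_equal(tie$nnt, Inf)
  harm <- nnt_at(ctl, act, 12)
  expect_true(harm$harm)
  expect_lt(harm$nnt, 0)
})

test_that("unanchored comparison is null-centered and weight-scale invariant", {
  reps <- vapply(1:60, function(r) {
    set.seed(3000 + r)
    a <- exp_arm(120, 0.06)
    b <- exp_arm(120, 0.06)
    s <- survival_sample(a$time, a$event, "ipd", weight = 1, endpoint = "os")
    log(unanchored_active_comparison(s, as_pseudo(b))$effect)
  }, numeric(1))
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)))

  set.seed(77)
  a <- exp_arm(150, 0.05)
  b <- exp_arm(150, 0.08)
  w <- runif(150, 0.3, 3)
  s1 <- survival_sample(a$time, a$event, "ipd", weight = w, endpoint = "os")
  s2 <- survival_sample(a$time, a$event, "ipd", weight = 5 * w, endpoint = "os")
  expect_equal(unanchored_active_comparison(s1, as_pseudo(b))$effect,
               unanchored_active_comparison(s2, as_pseudo(b))$effect,
               tolerance = 1e-6)
})

test_that("unanchored comparison recovers a configured active-vs-active effect", {
  truth <- log(0.5) - log(0.8)
  reps <- vapply(1:100, function(r) {
    dA <- simulate_trial(trial_config(n_per_arm = 200, seed = 4000 + r,
                                      baseline_hazard_os = 0.05,
                                      log_hr_treatment_os = log(0.5),
                                      censor_cutoff_months = 36))
    dB <- simulate_trial(trial_config(n_per_arm = 200, seed = 8000 + r,
                                      baseline_hazard_os = 0.05,
                                      log_hr_treatment_os = log(0.8),
                                      censor_cutoff_months = 36))
    Aa <- dA[dA$arm == "active", ]
    Ba <- dB[dB$arm == "active", ]
    s <- survival_sample(Aa$os_time, Aa$os_event, "ipd", endpoint = "os")
    log(unanchored_active_comparison(
      s, as_pseudo(data.frame(time = Ba$os_time, event = Ba$os_event)))$effect)
  }, numeric(1))
  expect_lt(abs(mean(reps) - truth), 3 * sd(reps) / sqrt(length(reps)))
})

test_that("anchored and unanchored contrasts agree in expectation under ideal conditions", {
  diffs <- vapply(1:80, function(r) {
    mk <- function(seed, eff) simulate_trial(trial_config(
      n_per_arm = 150, seed = seed, baseline_hazard_os = 0.06,
      log_hr_treatment_os = eff, censor_cutoff_months = 36))
    dA <- mk(1500 + r, log(0.5))
    dB <- mk(9000 + r, log(0.8))
    loghr <- function(d) unname(stats::coef(survival::coxph(
      survival::Surv(os_time, os_event) ~ I(arm == "active"), data = d)))
    anchored <- loghr(dA) - loghr(dB)
    Aa <- dA[dA$arm == "active", ]
    Ba <- dB[dB$arm == "active", ]
    s <- survival_sample(Aa$os_time, Aa$os_event, "ipd", endpoint = "os")
    unanch <- log(unanchored_active_comparison(
      s, as_pseudo(data.frame(time = Ba$os_time, event = Ba$os_event)))$effect)
    anchored - unanch
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("matching corrects the confounding bias an unadjusted contrast carries", {
  res <- vapply(1:80, confounded_pair_rep, numeric(2))
  mcse <- apply(res, 1, sd) / sqrt(ncol(res))
  expect_gt(abs(mean(res["unadjusted", ])), 3 * mcse["unadjusted"])
  expect_lt(abs(mean(res["adjusted", ])), 3 * mcse["adjusted"])
})

test_that("external control comparison feeds absolute-difference summaries", {
  set.seed(91)
  a <- exp_arm(800, 0.05)
  b <- exp_arm(800, 0.05)
  s <- survival_sample(a$time, a$event, "ipd", endpoint = "os")
  out <- external_control_comparison(s, as_pseudo(b))
  expect_equal(out$result$kind, "external_control")
  expect_gt(out$result$p_value, 0.05)   # identical laws: no detectable effect
  expect_true(out$result$ci_lower <= 1 && 1 <= out$result$ci_upper)
  nn <- nnt_at(out$km_active, out$km_control, 12)
  expect_s3_class(nn, "nnt_result")
})

test_that("the negative control detects residual imbalance in the induced direction", {
  # comparator population carries an unmeasured factor shortening PFS
  set.seed(55)
  ipd_placebo <- exp_arm(400, 0.10, cutoff = 30)
  comp_placebo <- exp_arm(400, 0.18, cutoff = 30)
  s <- survival_sample(ipd_placebo$time, ipd_placebo$event, "ipd_placebo",
                       endpoint = "pfs")
  res <- negative_control(s, as_pseudo(comp_placebo))
  expect_equal(res$kind, "negative_control")
  expect_lt(res$ci_upper, 1)   # IPD placebo progresses slower: HR below 1
  expect_match(res$note, "residual")

  # balanced populations leave the control null
  comp_null <- exp_arm(400, 0.10, cutoff = 30)
  res0 <- negative_control(s, as_pseudo(comp_null))
  expect_true(res0$ci_lower <= 1 && 1 <= res0$ci_upper)
})
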