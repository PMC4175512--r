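# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# brute-force weighted product-limit estimate at the event times
km_oracle <- function(time, event, w = rep(1, length(time))) {
  tt <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(w[time >= tt[i]])
    d <- sum(w[event & time == tt[i]])
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# hand-coded Cox partial log-likelihood for a scalar covariate (fixtures
# using it have no tied event times, so all tie conventions coincide)
cox_loglik <- function(beta, time, event, z, w = rep(1, length(time))) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + w[i] * (z[i] * beta - log(sum(w[risk] * exp(z[risk] * beta))))
  }
  ll
}

# two-stage grid search maximizer, final resolution `fine`
grid_maximize <- function(f, lower = -3, upper = 3, coarse = 0.01, fine = 1e-5) {
  g <- seq(lower, upper, by = coarse)
  b0 <- g[which.max(vapply(g, f, numeric(1)))]
  g2 <- seq(b0 - 2 * coarse, b0 + 2 * coarse, by = fine)
  g2[which.max(vapply(g2, f, numeric(1)))]
}

toy_cox_fixture <- function() {
  data.frame(time = c(1.1, 1.9, 3.2, 4.4, 5.3, 6.1),
             event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
             z = c(0, 1, 1, 0, 1, 0))
}

# one administratively censored exponential arm
exp_arm <- function(n, rate, cutoff = 40) {
  tt <- stats::rexp(n, rate)
  data.frame(time = pmin(tt, cutoff), event = tt <= cutoff)
}

# digitize an arm the way a published figure presents it
digitize_arm <- function(d, cutoff = 40, grid_step = 1, ar_step = 8,
                         arm = "", endpoint = "") {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  g <- seq(0, cutoff, by = grid_step)
  s <- summary(fit, times = g, extend = TRUE)$surv
  ar_t <- seq(0, cutoff, by = ar_step)
  list(curve = digitized_curve(g, s, arm = arm, endpoint = endpoint),
       at_risk = at_risk_table(ar_t, vapply(ar_t, function(x)
         sum(d$time >= x), numeric(1))))
}

# a pseudo_ipd wrapper for raw rows, for tests exercising the comparison
# machinery without re-running the reconstruction
as_pseudo <- function(d, arm = "", endpoint = "") {
  structure(data.frame(time = d$time, event = d$event),
            arm = arm, endpoint = endpoint,
            class = c("pseudo_ipd", "data.frame"))
}

# a weighted_km step object built directly from known coordinates, for tests
# whose contract is "given a curve" (e.g. number needed to treat)
km_steps <- function(time, surv) {
  structure(data.frame(time = time, surv = surv, lower = NA_real_,
                       upper = NA_real_),
            group = "", max_time = max(time),
            class = c("weighted_km", "data.frame"))
}

# 410 patients with exactly 15 performance-status-2 and 1 missing baseline
eligibility_fixture <- function(seed = 5) {
  ipd <- simulate_trial(example_ipd_config(seed))
  ipd$ecog[ipd$ecog == 2] <- 1L
  ipd$ecog[1:15] <- 2L
  ipd$prior_chemo[30] <- NA
  ipd
}

# paired-trial simulation with a prognostic covariate imbalanced across
# trials; active arms share the conditional law, so the matched contrast has
# true log hazard ratio 0 while the unadjusted contrast is confounded
confounded_pair_rep <- function(r, n_per_arm = 150) {
  shared <- list(n_per_arm = n_per_arm, baseline_hazard_os = 0.05,
                 log_hr_treatment_os = log(0.7),
                 covariate_log_hrs = c(ecog0 = -1.0),
                 censor_cutoff_months = 36)
  A <- simulate_trial(do.call(trial_config, c(shared, list(
    covariate_margins = list(ecog0 = 0.688), seed = 1000L + r))))
  B <- simulate_trial(do.call(trial_config, c(shared, list(
    covariate_margins = list(ecog0 = 0.55), seed = 500000L + r))))
  m <- target_margins(data.frame(covariate = "ecog0", kind = "proportion",
                                 target = 0.55))
  w <- maic(A, m)$weights
  Aa <- A[A$arm == "active", ]
  Ba <- B[B$arm == "active", ]
  pool <- function(wa) survival_sample(
    c(Aa$os_time, Ba$os_time), c(Aa$os_event, Ba$os_event),
    c(rep("A", nrow(Aa)), rep("B", nrow(Ba))),
    weight = c(wa, rep(1, nrow(Ba))), endpoint = "os")
  c(unadjusted = log(weighted_cox(pool(rep(1, nrow(Aa))), "B")$effect),
    adjusted = log(weighted_cox(pool(w[A$arm == "active"]), "B")$effect))
}

# memoized full example analysis (simulation + pipeline are reused across
# test files)
.fixture_cache <- new.env(parent = emptyenv())
example_run <- function(seed = 101) {
  key <- paste0("run", seed)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- example_analysis_config(seed = seed)
    .fixture_cache[[key]] <- list(cfg = cfg,
                                  res = suppressWarnings(run_analysis(cfg)))
  }
  .fixture_cache[[key]]
}
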