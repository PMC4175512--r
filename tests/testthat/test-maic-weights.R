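test_that("eligibility harmonization accounts for every exclusion", {
  ipd <- eligibility_fixture(seed = 5)
  expect_equal(nrow(ipd), 410)
  out <- apply_eligibility(ipd)
  expect_equal(nrow(out$records), 394)
  expect_equal(out$exclusions, c(ecog = 15, missing = 1))

  # identities
  none <- apply_eligibility(ipd, excluded_ecog_levels = integer(0),
                            drop_missing = FALSE)
  expect_equal(nrow(none$records), 410)
  expect_equal(unname(none$exclusions), c(0, 0))
  clean <- out$records
  again <- apply_eligibility(clean)
  expect_equal(nrow(again$records), nrow(clean))

  expect_error(apply_eligibility(ipd, excluded_ecog_levels = 0:2),
               "all patients excluded")
})

test_that("design matrix encodes medians, proportions and categorical levels", {
  rec <- simulate_trial(example_ipd_config(seed = 3))
  m <- target_margins(data.frame(
    covariate = c("age", "sites2", "sites3", "prior_chemo"),
    kind = c("median", "proportion", "proportion", "proportion"),
    target = c(56.5, 0.337, 0.349, 0.69)))
  d <- build_design(rec, m)
  expect_equal(colnames(d$X), c("age", "sites2", "sites3", "prior_chemo"))
  # median margin: indicator of exceeding the reported median, target one half
  expect_equal(unname(d$X[, "age"]), as.numeric(rec$age > 56.5))
  expect_equal(unname(d$targets["age"]), 0.5)
  # categorical levels: one indicator per non-reference level
  expect_equal(unname(d$X[, "sites2"]), as.numeric(rec$n_disease_sites == "2"))
  expect_equal(unname(d$targets[c("sites2", "sites3")]), c(0.337, 0.349))
  expect_error(build_design(rec, target_margins(data.frame(
    covariate = "karnofsky", kind = "proportion", target = 0.5))),
    "karnofsky")
})

test_that("single-covariate weights solve the moment equation in closed form", {
  X <- matrix(c(1, 1, 1, 0), dimnames = list(NULL, "x"))
  fit <- estimate_weights(X, c(x = 0.5))
  # 3 w1 (0.5) + w0 (-0.5) = 0  =>  w1/w0 = 1/3
  expect_equal(fit$weights[1] / fit$weights[4], 1 / 3, tolerance = 1e-10)
  expect_equal(sum(fit$weights * X) / sum(fit$weights), 0.5, tolerance = 1e-12)

  # null match: targets at the sample means leave the weights uniform
  set.seed(1)
  X2 <- cbind(a = rbinom(50, 1, 0.4), b = rbinom(50, 1, 0.7))
  fit2 <- estimate_weights(X2, colMeans(X2))
  expect_equal(unname(fit2$coefficients), c(0, 0), tolerance = 1e-8)
  expect_lt(diff(range(fit2$weights)), 1e-8)
  expect_equal(fit2$ess, 50, tolerance = 1e-6)
})

test_that("optimizer agrees with a bisection root of the moment equation", {
  x <- c(0, 0, 1, 1, 1, 1)
  target <- 0.45
  moment <- function(b) sum((x - target) * exp(b * (x - target)))
  lo <- -20; hi <- 20
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (moment(mid) > 0) hi <- mid else lo <- mid
  }
  fit <- estimate_weights(matrix(x, dimnames = list(NULL, "x")),
                          c(x = target))
  expect_equal(unname(fit$coefficients), (lo + hi) / 2, tolerance = 1e-6)
})

test_that("weighting achieves exact balance at the reported margins", {
  rec <- apply_eligibility(simulate_trial(example_ipd_config(seed = 41)))$records
  fit <- maic(rec, example_margins())
  expect_true(fit$converged)
  expect_lt(fit$max_balance_error, 1e-8)
  w <- fit$weights
  d <- build_design(rec, example_margins())
  for (j in colnames(d$X))
    expect_equal(sum(w * d$X[, j]) / sum(w), unname(d$targets[j]),
                 tolerance = 1e-8)
  expect_lte(fit$ess, nrow(rec))
  expect_lt(fit$ess, nrow(rec))  # non-trivial reweighting shrinks the ESS
  expect_true(all(w >= 0))
  # display scale: normalized to sum to the ESS, estimation scale unchanged
  expect_equal(sum(weights(fit, scale = "ess")), fit$ess)
})

test_that("infeasible targets are reported as separation, not tolerance failure", {
  X <- matrix(c(0, 0, 0, 1), dimnames = list(NULL, "x"))
  expect_error(estimate_weights(X, c(x = 1)), "convex hull|separation")
  expect_error(estimate_weights(X, c(x = 0)), "convex hull|separation")
  # extreme but feasible targets still converge, at the cost of the ESS
  fit99 <- estimate_weights(X, c(x = 0.9))
  expect_lt(fit99$max_balance_error, 1e-8)
  expect_lt(fit99$ess, 2)
  # a constant column already at its target is fine
  Xc <- cbind(x = c(1, 0, 1, 0), k = c(1, 1, 1, 1))
  fitc <- estimate_weights(Xc, c(x = 0.5, k = 1))
  expect_lt(fitc$max_balance_error, 1e-10)
})

test_that("effective sample size equals n exactly when weights are constant", {
  w_const <- rep(2.5, 40)
  expect_equal(sum(w_const)^2 / sum(w_const^2), 40)
  w_var <- c(rep(1, 39), 5)
  expect_lt(sum(w_var)^2 / sum(w_var^2), 40)
})

test_that("baseline comparability tests match the contingency-table oracle", {
  # the performance-status imbalance: 68.8% of 394 vs 55.0% of 171
  rec <- data.frame(ecog = c(rep(0L, 271), rep(1L, 123)))
  m <- target_margins(data.frame(covariate = "ecog0", kind = "proportion",
                                 target = 0.55))
  out <- balance_tests(rec, m, comparator_n = 171)
  expect_true(out$flagged)
  # oracle: hand-built 2x2 chi-square on the same counts
  tab <- rbind(c(271, 394 - 271), c(94, 171 - 94))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - e)^2 / e)
  expect_equal(out$statistic, chi2, tolerance = 1e-10)

  # identical distributions are not flagged
  set.seed(8)
  rec2 <- data.frame(ecog = rbinom(394, 1, 0.45))
  m2 <- target_margins(data.frame(covariate = "ecog0", kind = "proportion",
                                  target = mean(rec2$ecog == 0)))
  expect_false(balance_tests(rec2, m2, comparator_n = 171)$flagged)

  expect_error(balance_tests(rec, m, comparator_n = NULL), "sample size")
})
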