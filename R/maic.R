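# Normal quantile used throughout for 95% intervals; the full-precision value
# keeps CI endpoints deterministic across platforms.
.z975 <- 1.959964

#' Reported baseline margins of the aggregate trial
#'
#' The matching targets: for each baseline characteristic, either the reported
#' proportion (binary or categorical level) or the reported median
#' (continuous).
#'
#' @param entries data.frame with columns `covariate` (feature name, see
#'   [covariate_feature()]), `kind` (`"proportion"` or `"median"`), and
#'   `target` (the reported value; proportions on the 0-1 scale).
#' @param source free-text label for provenance (trial name, table).
#' @return object of class `target_margins`.
#' @export
target_margins <- function(entries, source = "") {
  stopifnot(is.data.frame(entries),
            all(c("covariate", "kind", "target") %in% names(entries)))
  if (anyDuplicated(entries$covariate))
    stop("each covariate may appear only once in the margins")
  if (!all(entries$kind %in% c("proportion", "median")))
    stop("margin kind must be 'proportion' or 'median'")
  p <- entries$target[entries$kind == "proportion"]
  if (any(p < 0 | p > 1)) stop("proportion targets must lie in [0, 1]")
  structure(list(entries = entries[c("covariate", "kind", "target")],
                 source = source),
            class = "target_margins")
}

#' @export
print.target_margins <- function(x, ...) {
  cat("Target margins", if (nzchar(x$source)) paste0(" (", x$source, ")"),
      ":\n", sep = "")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Harmonize trial eligibility before matching
#'
#' Removes patients whose baseline performance status was not eligible for the
#' comparator trial, and (optionally) patients with missing values in any
#' matched covariate, mirroring complete-case handling before weighting.
#'
#' @param records patient records.
#' @param excluded_ecog_levels integer vector of WHO/ECOG levels to drop
#'   (default 2: ambulatory but unable to work, excluded by the comparator
#'   trial's design).
#' @param drop_missing drop rows with missing values in `covariates`?
#' @param covariates columns checked for missingness.
#' @return list with `records` (retained rows) and `exclusions` (named counts
#'   per reason: `ecog`, `missing`).
#' @export
apply_eligibility <- function(records, excluded_ecog_levels = 2L,
                              drop_missing = TRUE,
                              covariates = c("age", "sex", "ecog",
                                             "time_since_dx_ge3y",
                                             "n_disease_sites", "distant_mets",
                                             "prior_ssa", "prior_chemo")) {
  covariates <- intersect(covariates, names(records))
  drop_ecog <- records$ecog %in% excluded_ecog_levels
  miss <- rep(FALSE, nrow(records))
  if (drop_missing && length(covariates))
    miss <- rowSums(is.na(records[covariates])) > 0
  miss <- miss & !drop_ecog  # count each exclusion once, eligibility first
  keep <- !(drop_ecog | miss)
  if (!any(keep)) stop("apply_eligibility: all patients excluded")
  list(records = records[keep, , drop = FALSE],
       exclusions = c(ecog = sum(drop_ecog), missing = sum(miss)))
}

#' Build the matching design matrix and target vector
#'
#' Binary covariates become 0/1 columns with the reported proportion as
#' target. Median targets become the indicator `1{value > reported median}`
#' with target 0.5 (ties at the median count as below; the convention is
#' documented because the reports are silent on it). Multi-level categorical
#' covariates enter as k-1 indicator columns with the reference level omitted.
#'
#' @param records patient records.
#' @param margins a [target_margins()].
#' @return list with `X` (n x p numeric matrix, columns named by margin
#'   covariate) and `targets` (named vector, same order).
#' @export
build_design <- function(records, margins) {
  stopifnot(inherits(margins, "target_margins"))
  e <- margins$entries
  cols <- vector("list", nrow(e))
  targets <- numeric(nrow(e))
  for (i in seq_len(nrow(e))) {
    x <- tryCatch(covariate_feature(records, e$covariate[i]),
                  error = function(err)
                    stop("build_design: cannot resolve covariate '",
                         e$covariate[i], "'", call. = FALSE))
    if (e$kind[i] == "median") {
      cols[[i]] <- as.numeric(x > e$target[i])
      targets[i] <- 0.5
    } else {
      cols[[i]] <- x
      targets[i] <- e$target[i]
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- e$covariate
  names(targets) <- e$covariate
  if (anyNA(X)) stop("build_design: missing covariate values; apply eligibility first")
  list(X = X, targets = targets)
}

#' Method-of-moments exponential-tilting weights
#'
#' Solves for per-patient weights `w_i = exp(x_i' beta)` such that the
#' weighted means of all matched columns equal their targets exactly. The
#' coefficients minimize the convex objective `sum_i exp(z_i' beta)` over
#' covariates `z_i = x_i - target` centered at their targets; the first-order
#' condition of that minimization is exactly the moment match. This is the
#' standard matching-adjusted indirect comparison estimator: each weight is
#' proportional to the patient's relative odds of enrolment in the
#' aggregate-data trial under a logistic enrolment model, which cannot be fit
#' directly because comparator individual data do not exist.
#'
#' Solved by Newton iterations with step halving on the exact gradient and
#' Hessian.
#'
#' @param X design matrix from [build_design()].
#' @param targets named target vector from [build_design()].
#' @param tol convergence tolerance on the maximum absolute difference
#'   between weighted means and targets.
#' @param max_iter maximum Newton iterations.
#' @return list: `weights` (raw, mean exp-score scale), `coefficients`,
#'   `ess` (effective sample size `(sum w)^2 / sum w^2`), `converged`,
#'   `balance` (per-covariate pre-match mean, post-match weighted mean,
#'   target), `max_balance_error`.
#' @export
estimate_weights <- function(X, targets, tol = 1e-10, max_iter = 200L) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(targets))
  # feasibility: each target strictly inside the column's observed range,
  # otherwise no finite tilting coefficient exists (separation)
  rng <- apply(X, 2, range)
  bad <- targets <= rng[1, ] | targets >= rng[2, ]
  at_mean <- abs(targets - colMeans(X)) < .Machine$double.eps^0.5
  bad <- bad & !at_mean  # a degenerate constant column matching its target is fine
  if (any(bad))
    stop("estimate_weights: target for ",
         paste(colnames(X)[bad], collapse = ", "),
         " lies outside the convex hull of the data (separation); ",
         "no weight solution exists")

  Z <- sweep(X, 2, targets)
  beta <- numeric(ncol(X))
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    s <- drop(Z %*% beta)
    w <- exp(s - max(s))             # scale-free: objective is homogeneous
    grad <- drop(crossprod(Z, w))
    err <- max(abs(grad)) / sum(w)   # = max |weighted mean - target|
    if (err <= tol) { conv <- TRUE; break }
    H <- crossprod(Z * w, Z)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      H <- H + diag(1e-10 * max(diag(H)), ncol(H))
      step <- solve(H, grad)
    }
    # step halving on the objective sum(exp(Z beta)); the relative guard keeps
    # full Newton steps near the optimum, where the decrease is below the
    # objective's floating-point resolution
    obj <- sum(w)
    lam <- 1
    repeat {
      cand <- beta - lam * step
      s2 <- drop(Z %*% cand)
      if (sum(exp(s2 - max(s))) <= obj * (1 + 1e-9) || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- beta - lam * step
  }
  s <- drop(Z %*% beta)
  w <- exp(s - mean(s))
  wm <- drop(crossprod(X, w)) / sum(w)
  err <- max(abs(wm - targets))
  if (!conv && err > 1e-6)
    stop("estimate_weights: no convergence after ", max_iter,
         " iterations (max balance error ", format(err, digits = 3),
         "); targets may be near the boundary of feasibility")
  ess <- sum(w)^2 / sum(w^2)
  balance <- data.frame(covariate = colnames(X),
                        pre_match = colMeans(X),
                        post_match = wm,
                        target = unname(targets),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(weights = w, coefficients = stats::setNames(beta, colnames(X)),
       ess = ess, converged = conv, balance = balance,
       max_balance_error = err)
}

#' Fit a matching-adjusted indirect comparison weight model
#'
#' The central fitting function: reweights individual patient data so that
#' the weighted baseline medians and proportions exactly match the margins
#' reported for an aggregate-data comparator trial. See [estimate_weights()]
#' for the estimator.
#'
#' @param data patient records (one row per patient).
#' @param margins a [target_margins()] holding the comparator's reported
#'   values.
#' @param tol,max_iter passed to [estimate_weights()].
#' @return object of class `maic`: components `weights` (raw, one per row of
#'   `data`), `coefficients` (enrolment-model log-odds coefficients), `ess`,
#'   `converged`, `balance`, `n`, `margins`, `call`. Methods: `print`,
#'   `summary`, `coef`, `weights`, `plot`.
#' @examples
#' cfg <- trial_config(n_per_arm = 100, seed = 7,
#'                     covariate_margins = list(ecog0 = 0.69, prior_chemo = 0.49))
#' ipd <- simulate_trial(cfg)
#' m <- target_margins(data.frame(
#'   covariate = c("ecog0", "prior_chemo"),
#'   kind = "proportion", target = c(0.55, 0.69)))
#' fit <- maic(ipd, m)
#' summary(fit)
#' @export
maic <- function(data, margins, tol = 1e-10, max_iter = 200L) {
  d <- build_design(data, margins)
  fit <- estimate_weights(d$X, d$targets, tol = tol, max_iter = max_iter)
  structure(c(fit, list(n = nrow(data), margins = margins,
                        call = match.call())),
            class = "maic")
}

#' @export
print.maic <- function(x, digits = 4, ...) {
  cat("Matching-adjusted indirect comparison weights\n")
  cat(sprintf("  patients: %d   effective sample size: %.1f (%.1f%%)\n",
              x$n, x$ess, 100 * x$ess / x$n))
  cat(sprintf("  matched covariates: %d   max balance error: %.2g\n",
              length(x$coefficients), x$max_balance_error))
  if (!x$converged) cat("  WARNING: weight model did not converge\n")
  invisible(x)
}

#' @export
summary.maic <- function(object, ...) {
  structure(list(fit = object), class = "summary.maic")
}

#' @export
print.summary.maic <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nEnrolment-model coefficients (log odds per unit):\n")
  print(round(x$fit$coefficients, digits))
  cat("\nBalance (pre-match mean, weighted mean, target):\n")
  b <- x$fit$balance
  b[-1] <- lapply(b[-1], round, digits)
  print(b, row.names = FALSE)
  invisible(x)
}

#' @export
coef.maic <- function(object, ...) object$coefficients

#' Extract MAIC weights
#'
#' @param object a fitted [maic()] object.
#' @param scale `"raw"` for the weights used in estimation, `"ess"` for
#'   weights normalized to sum to the effective sample size (the
#'   reviewer-friendly display scale; all weighted estimates are invariant to
#'   the choice).
#' @param ... unused.
#' @return numeric vector, one weight per patient.
#' @export
weights.maic <- function(object, scale = c("raw", "ess"), ...) {
  scale <- match.arg(scale)
  w <- object$weights
  if (scale == "ess") w <- w * object$ess / sum(w)
  w
}

#' Balance plot for a MAIC fit
#'
#' Dot chart of pre-match means, post-match weighted means and targets for
#' each matched covariate.
#'
#' @param x a [maic()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.maic <- function(x, ...) {
  b <- x$balance
  k <- nrow(b)
  graphics::plot(b$pre_match, seq_len(k), xlim = range(b[-1]), pch = 1,
                 yaxt = "n", ylab = "", xlab = "mean / proportion",
                 main = "Covariate balance", ...)
  graphics::axis(2, at = seq_len(k), labels = b$covariate, las = 1)
  graphics::points(b$post_match, seq_len(k), pch = 16)
  graphics::points(b$target, seq_len(k), pch = 4, col = 2)
  graphics::legend("topleft", pch = c(1, 16, 4), col = c(1, 1, 2),
                   legend = c("pre-match", "post-match", "target"), bty = "n")
  invisible(x)
}

#' Pre-matching baseline comparability tests
#'
#' Compares each reported margin with the unweighted individual-patient
#' sample: two-sample chi-square tests (without continuity correction) for
#' proportions, reconstructing comparator counts from the reported proportion
#' and sample size; a one-sample t approximation against the reported median
#' for continuous covariates (only the median is published, so the reported
#' value stands in for the comparator location).
#'
#' @param records patient records (unweighted).
#' @param margins a [target_margins()].
#' @param comparator_n reported sample size of the aggregate trial.
#' @param alpha significance level for flagging (default 0.05).
#' @return data.frame: covariate, kind, ipd value, reported value, test
#'   statistic, p-value, and a `flagged` logical.
#' @export
balance_tests <- function(records, margins, comparator_n, alpha = 0.05) {
  if (missing(comparator_n) || is.null(comparator_n) || is.na(comparator_n))
    stop("balance_tests: comparator sample size is required")
  e <- margins$entries
  out <- e
  out$ipd_value <- NA_real_
  out$statistic <- NA_real_
  out$p_value <- NA_real_
  n1 <- nrow(records)
  for (i in seq_len(nrow(e))) {
    x <- covariate_feature(records, e$covariate[i])
    if (e$kind[i] == "proportion") {
      x1 <- sum(x)
      x2 <- round(e$target[i] * comparator_n)
      tab <- rbind(c(x1, n1 - x1), c(x2, comparator_n - x2))
      ts <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out$ipd_value[i] <- mean(x)
      out$statistic[i] <- unname(ts$statistic)
      out$p_value[i] <- ts$p.value
    } else {
      tt <- stats::t.test(x, mu = e$target[i])
      out$ipd_value[i] <- stats::median(x)
      out$statistic[i] <- unname(tt$statistic)
      out$p_value[i] <- tt$p.value
    }
  }
  out$flagged <- out$p_value < alpha
  names(out)[names(out) == "target"] <- "reported"
  out[c("covariate", "kind", "ipd_value", "reported",
        "statistic", "p_value", "flagged")]
}
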