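#' Assemble a (possibly weighted) survival sample
#'
#' @param time event/censoring times in months.
#' @param event event indicator.
#' @param group group label per row.
#' @param weight nonnegative weight per row (default 1).
#' @param endpoint endpoint label (e.g. `"os"`, `"pfs"`).
#' @return data.frame of class `survival_sample`.
#' @export
survival_sample <- function(time, event, group, weight = 1, endpoint = "") {
  weight <- rep_len(weight, length(time))
  stopifnot(all(time >= 0), all(weight >= 0))
  structure(data.frame(time = time, event = as.logical(event),
                       group = as.character(group), weight = weight),
            endpoint = endpoint, class = c("survival_sample", "data.frame"))
}

#' Weighted Kaplan-Meier curve
#'
#' Product-limit estimate with weighted risk sets and weighted event counts,
#' with log-scale pointwise confidence intervals.
#'
#' @param sample a [survival_sample()].
#' @param group which group to estimate; default: the only group present.
#' @return object of class `weighted_km`: data.frame (`time`, `surv`,
#'   `lower`, `upper`) plus attributes `group`, `max_time`.
#' @export
weighted_km <- function(sample, group = NULL) {
  if (is.null(group)) {
    group <- unique(sample$group)
    if (length(group) != 1) stop("weighted_km: specify which group to estimate")
  }
  d <- sample[sample$group == group & sample$weight > 0, , drop = FALSE]
  if (nrow(d) == 0) stop("weighted_km: empty group '", group, "'")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                           weights = d$weight, conf.type = "log")
  structure(data.frame(time = fit$time, surv = fit$surv,
                       lower = fit$lower, upper = fit$upper),
            group = group, max_time = max(d$time),
            class = c("weighted_km", "data.frame"))
}

#' Survival probability at a time point
#'
#' Step-function lookup on a [weighted_km()] curve: the product-limit value
#' carried forward from the last event time at or before `t`. Times beyond
#' the observed follow-up return the last value with an `extrapolated` flag.
#'
#' @param curve a `weighted_km` object.
#' @param t time in months (>= 0).
#' @return survival probability with attribute `extrapolated`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(t >= 0)
  idx <- which(curve$time <= t + 1e-12)
  s <- if (length(idx) == 0) 1 else curve$surv[max(idx)]
  structure(s, extrapolated = t > attr(curve, "max_time"))
}

#' Weighted Cox proportional-hazards comparison of two groups
#'
#' Maximizes the weighted partial likelihood for a single group indicator
#' (Efron tie handling) and reports the hazard ratio with a weight-robust
#' sandwich variance, Wald confidence interval and p-value. Weights are
#' treated as fixed, the standard practice for matching-adjusted weights.
#'
#' @param sample a [survival_sample()] with exactly two groups.
#' @param reference_group label of the denominator group.
#' @param kind provenance tag stored on the result.
#' @return a [comparison_result()].
#' @export
weighted_cox <- function(sample, reference_group, kind = "unanchored_active") {
  groups <- unique(sample$group)
  if (length(groups) != 2) stop("weighted_cox: exactly two groups required")
  if (!reference_group %in% groups)
    stop("weighted_cox: reference group '", reference_group, "' not present")
  other <- setdiff(groups, reference_group)
  ev <- tapply(sample$event & sample$weight > 0, sample$group, sum)
  if (any(ev == 0))
    stop("weighted_cox: no events in group '", names(ev)[ev == 0][1],
         "'; hazard ratio non-estimable (monotone likelihood)")
  d <- sample
  d$z <- as.numeric(d$group == other)
  fit <- survival::coxph(survival::Surv(time, event) ~ z, data = d,
                         weights = d$weight, ties = "efron", robust = TRUE)
  b <- unname(stats::coef(fit))
  se <- sqrt(fit$var[1, 1])   # robust sandwich when robust = TRUE
  ess_by <- tapply(d$weight, d$group, function(w) sum(w)^2 / sum(w^2))
  comparison_result(effect = exp(b), ci_lower = exp(b - .z975 * se),
                    ci_upper = exp(b + .z975 * se),
                    p_value = 2 * stats::pnorm(-abs(b / se)),
                    log_se = se, kind = kind,
                    n_effective = ess_by[c(other, reference_group)])
}

#' A cross-trial comparison result
#'
#' Container for an estimated hazard ratio or odds ratio with its confidence
#' interval, p-value and provenance.
#'
#' @param effect point estimate (HR or OR).
#' @param ci_lower,ci_upper 95% confidence bounds, same scale.
#' @param p_value two-sided Wald p-value.
#' @param log_se standard error of the log effect.
#' @param kind one of `"anchored"`, `"unanchored_active"`,
#'   `"external_control"`, `"negative_control"`, `"adverse_event"`.
#' @param n_effective optional named effective sample sizes per group.
#' @param note optional interpretation note.
#' @return object of class `maic_comparison`.
#' @export
comparison_result <- function(effect, ci_lower, ci_upper, p_value, log_se,
                              kind, n_effective = NULL, note = NULL) {
  kind <- match.arg(kind, c("anchored", "unanchored_active",
                            "external_control", "negative_control",
                            "adverse_event"))
  stopifnot(effect > 0, ci_lower > 0, ci_upper > 0,
            ci_lower <= effect + 1e-12, effect <= ci_upper + 1e-12)
  structure(list(effect = unname(effect), ci_lower = unname(ci_lower),
                 ci_upper = unname(ci_upper), p_value = unname(p_value),
                 log_se = unname(log_se), kind = kind,
                 n_effective = n_effective, note = note),
            class = "maic_comparison")
}

#' @export
print.maic_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("%s comparison: %.2f (95%% CI %.2f-%.2f), p = %s\n",
              x$kind, x$effect, x$ci_lower, x$ci_upper,
              format.pval(x$p_value, digits = digits)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
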