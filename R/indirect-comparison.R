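#' A published relative effect with its confidence interval
#'
#' @param hr published hazard ratio (or odds ratio).
#' @param ci_lower,ci_upper published 95% bounds.
#' @param endpoint endpoint label.
#' @param trial trial label.
#' @return object of class `published_effect`.
#' @export
published_effect <- function(hr, ci_lower, ci_upper, endpoint = "", trial = "") {
  if (!(0 < ci_lower && ci_lower <= hr && hr <= ci_upper))
    stop("published_effect: require 0 < ci_lower <= hr <= ci_upper")
  structure(list(hr = hr, ci_lower = ci_lower, ci_upper = ci_upper,
                 endpoint = endpoint, trial = trial),
            class = "published_effect")
}

#' Back-calculate the log-scale standard error from a 95% CI
#'
#' `SE = (ln upper - ln lower) / (2 * 1.959964)`, assuming the interval was
#' Wald-type on the log scale.
#'
#' @param effect a [published_effect()].
#' @return standard error of the log effect.
#' @export
se_from_ci <- function(effect) {
  stopifnot(inherits(effect, "published_effect"))
  if (effect$ci_lower <= 0) stop("se_from_ci: nonpositive bounds")
  (log(effect$ci_upper) - log(effect$ci_lower)) / (2 * .z975)
}

.log_effect <- function(x) {
  if (inherits(x, "published_effect"))
    list(b = log(x$hr), se = se_from_ci(x), endpoint = x$endpoint)
  else if (inherits(x, "maic_comparison"))
    list(b = log(x$effect), se = x$log_se, endpoint = NA_character_)
  else stop("expected a published_effect or maic_comparison")
}

#' Anchored indirect comparison through a common comparator
#'
#' Combines two relative effects that share a comparator arm (A vs B and
#' C vs B) into the indirect contrast A vs C: log effects subtract and
#' squared standard errors add, with a Wald interval and p-value. Relying
#' only on within-trial relative effects preserves randomization in both
#' trials.
#'
#' @param effect_ab A-vs-comparator effect: a [published_effect()] or a
#'   fitted [weighted_cox()] result.
#' @param effect_cb C-vs-comparator effect, same comparator and endpoint.
#' @param check_endpoint require matching endpoint labels when both inputs
#'   carry one (default TRUE).
#' @return a [comparison_result()] of kind `"anchored"` for A vs C.
#' @examples
#' ab <- published_effect(0.38, 0.29, 0.49, endpoint = "pfs")
#' cb <- published_effect(0.42, 0.26, 0.66, endpoint = "pfs")
#' bucher(ab, cb)  # 0.90 (0.53-1.53)
#' @export
bucher <- function(effect_ab, effect_cb, check_endpoint = TRUE) {
  a <- .log_effect(effect_ab)
  b <- .log_effect(effect_cb)
  if (check_endpoint && !is.na(a$endpoint) && !is.na(b$endpoint) &&
      nzchar(a$endpoint) && nzchar(b$endpoint) && a$endpoint != b$endpoint)
    stop("bucher: endpoint mismatch ('", a$endpoint, "' vs '", b$endpoint, "')")
  est <- a$b - b$b
  se <- sqrt(a$se^2 + b$se^2)
  comparison_result(effect = exp(est),
                    ci_lower = exp(est - .z975 * se),
                    ci_upper = exp(est + .z975 * se),
                    p_value = 2 * stats::pnorm(-abs(est / se)),
                    log_se = se, kind = "anchored")
}

.pool_with_pseudo <- function(weighted_arm, pseudo_arm, ipd_label, pseudo_label) {
  stopifnot(inherits(weighted_arm, "survival_sample"),
            inherits(pseudo_arm, "pseudo_ipd"))
  if (is.null(weighted_arm$weight) || anyNA(weighted_arm$weight))
    stop("matching weights missing on the individual-patient arm")
  # normalize the IPD weights to sum to their effective sample size: the
  # pooled fit depends on the scale of one arm's weights relative to the
  # other's unit weights, and the ESS scale makes the weighted arm carry
  # exactly its information content (and the result invariant to the
  # arbitrary scale of the estimated weights)
  w <- weighted_arm$weight * sum(weighted_arm$weight) /
    sum(weighted_arm$weight^2)
  survival_sample(
    time = c(weighted_arm$time, pseudo_arm$time),
    event = c(weighted_arm$event, pseudo_arm$event),
    group = c(rep(ipd_label, nrow(weighted_arm)),
              rep(pseudo_label, nrow(pseudo_arm))),
    weight = c(w, rep(1, nrow(pseudo_arm))),
    endpoint = attr(weighted_arm, "endpoint"))
}

#' Unanchored comparison of two active arms across trials
#'
#' Pools the matching-weighted IPD active arm with the reconstructed
#' comparator active arm (unit weights) and fits a weighted
#' proportional-hazards model. Used when crossover contaminates the placebo
#' arms so relative effects cannot be anchored. Valid only if the weighting
#' balanced all prognostic cross-trial differences.
#'
#' Before pooling, the IPD weights are normalized to sum to their effective
#' sample size: in a pooled fit only the scale of one arm's weights relative
#' to the other arm's unit weights matters, and the effective-sample-size
#' scale both removes the arbitrary scale of the estimated weights and lets
#' the weighted arm carry exactly its information content.
#'
#' @param weighted_ipd_arm a [survival_sample()] for the IPD active arm,
#'   carrying the trial-wide matching weights.
#' @param pseudo_arm the comparator active arm as [reconstruct_pseudo_ipd()]
#'   output.
#' @param ipd_label,pseudo_label group labels.
#' @return a [comparison_result()] of kind `"unanchored_active"`
#'   (IPD arm vs pseudo arm).
#' @export
unanchored_active_comparison <- function(weighted_ipd_arm, pseudo_arm,
                                         ipd_label = "ipd_active",
                                         pseudo_label = "comparator_active") {
  pooled <- .pool_with_pseudo(weighted_ipd_arm, pseudo_arm, ipd_label, pseudo_label)
  weighted_cox(pooled, reference_group = pseudo_label, kind = "unanchored_active")
}

#' Compare the IPD active arm with an external control arm
#'
#' Treats the comparator trial's placebo arm (reconstructed from its
#' published curve) as an external control population for the
#' matching-weighted IPD active arm. Returns the hazard ratio and both
#' weighted Kaplan-Meier curves so absolute differences (and numbers needed
#' to treat) can be read off.
#'
#' @inheritParams unanchored_active_comparison
#' @param pseudo_placebo the external control arm's `pseudo_ipd`.
#' @return list of class `external_control_comparison`: `result` (a
#'   [comparison_result()] of kind `"external_control"`), `km_active`,
#'   `km_control`.
#' @export
external_control_comparison <- function(weighted_ipd_arm, pseudo_placebo,
                                        ipd_label = "ipd_active",
                                        pseudo_label = "external_control") {
  pooled <- .pool_with_pseudo(weighted_ipd_arm, pseudo_placebo,
                              ipd_label, pseudo_label)
  res <- weighted_cox(pooled, reference_group = pseudo_label,
                      kind = "external_control")
  list(result = res,
       km_active = weighted_km(pooled, ipd_label),
       km_control = weighted_km(pooled, pseudo_label))
}

#' Number needed to treat at a fixed horizon
#'
#' `NNT = 1 / (S_active(h) - S_control(h))`: the number of patients who must
#' receive the active therapy rather than control for one additional patient
#' to be event-free at the horizon. A negative survival difference yields a
#' negative value, reported as number needed to harm; a zero difference gives
#' an infinite NNT with a flag.
#'
#' @param km_active,km_control [weighted_km()] curves.
#' @param horizon months.
#' @return object of class `nnt_result`: `horizon`, `surv_active`,
#'   `surv_control`, `nnt`, flags `harm`, `infinite`, `extrapolated`.
#' @export
nnt_at <- function(km_active, km_control, horizon) {
  sa <- survival_at(km_active, horizon)
  sc <- survival_at(km_control, horizon)
  diff <- as.numeric(sa) - as.numeric(sc)
  structure(list(horizon = horizon,
                 surv_active = as.numeric(sa), surv_control = as.numeric(sc),
                 nnt = if (diff == 0) Inf else 1 / diff,
                 harm = diff < 0, infinite = diff == 0,
                 extrapolated = attr(sa, "extrapolated") || attr(sc, "extrapolated")),
            class = "nnt_result")
}

#' @export
print.nnt_result <- function(x, ...) {
  lab <- if (x$infinite) "undefined (equal survival)"
         else sprintf("%.1f%s", abs(x$nnt), if (x$harm) " (harm)" else "")
  cat(sprintf("NNT at %g months: %s  [S_active = %.2f, S_control = %.2f]%s\n",
              x$horizon, lab, x$surv_active, x$surv_control,
              if (x$extrapolated) "  (extrapolated)" else ""))
  invisible(x)
}

#' Placebo-arm negative-control comparison
#'
#' Compares progression-free survival between the weighted IPD placebo arm
#' and the comparator trial's reconstructed placebo arm. PFS is not affected
#' by post-progression crossover, so if the weighting balanced all relevant
#' characteristics this hazard ratio should be 1; a deviation indicates the
#' magnitude and direction of residual cross-trial imbalance.
#'
#' @param weighted_ipd_placebo_pfs [survival_sample()] of the IPD placebo
#'   arm's PFS, carrying the matching weights.
#' @param pseudo_placebo_pfs the comparator placebo arm's PFS `pseudo_ipd`.
#' @return a [comparison_result()] of kind `"negative_control"` with an
#'   interpretation note attached.
#' @export
negative_control <- function(weighted_ipd_placebo_pfs, pseudo_placebo_pfs) {
  pooled <- .pool_with_pseudo(weighted_ipd_placebo_pfs, pseudo_placebo_pfs,
                              "ipd_placebo", "comparator_placebo")
  res <- weighted_cox(pooled, reference_group = "comparator_placebo",
                      kind = "negative_control")
  res$note <- paste("a hazard ratio different from 1 indicates the magnitude",
                    "and direction of residual cross-trial imbalance",
                    "affecting progression-free survival")
  res
}
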