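#' Censor adverse-event counts at the comparator's follow-up
#'
#' Adverse events were monitored for longer in the IPD trial than in the
#' comparator trial, so raw incidence is not comparable. Each arm's events
#' are counted only if their onset falls at or before the matched
#' comparator arm's maximum follow-up time.
#'
#' @param records patient records with `ae_<name>` flags and
#'   `ae_<name>_onset` times.
#' @param ae_names adverse events to tabulate (without the `ae_` prefix).
#' @param cutoffs named vector `c(active = months, placebo = months)`; `Inf`
#'   keeps all events.
#' @return data.frame of class `ae_table`: one row per (ae, arm) with
#'   `events`, `n`, `rate`, `cutoff`.
#' @export
censor_ae_followup <- function(records, ae_names,
                               cutoffs = c(active = Inf, placebo = Inf)) {
  arms <- c("active", "placebo")
  rows <- list()
  for (ae in ae_names) {
    flag_col <- paste0("ae_", ae)
    onset_col <- paste0("ae_", ae, "_onset")
    if (is.null(records[[flag_col]]))
      stop("censor_ae_followup: no flag column for AE '", ae, "'")
    flags <- records[[flag_col]]
    onsets <- records[[onset_col]]
    if (is.null(onsets) || any(flags & is.na(onsets)))
      stop("censor_ae_followup: missing onset times for AE '", ae, "'")
    for (a in arms) {
      idx <- records$arm == a
      cut <- cutoffs[[a]]
      ev <- sum(flags[idx] & onsets[idx] <= cut, na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        ae = ae, arm = a, events = ev, n = sum(idx),
        rate = ev / sum(idx), cutoff = cut, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("ae_table", "data.frame"))
}

# weighted 2x2 cells for one AE in the IPD trial: weighted rates converted to
# effective counts (ESS scale) so the variance is not anti-conservative
.weighted_cells <- function(records, ae, weights) {
  flag <- records[[paste0("ae_", ae)]]
  vapply(c("active", "placebo"), function(a) {
    idx <- records$arm == a
    w <- weights[idx]
    ess <- sum(w)^2 / sum(w^2)
    p <- sum(w * flag[idx]) / sum(w)
    c(events = ess * p, n = ess)
  }, numeric(2))
}

#' Placebo-adjusted adverse-event odds ratios across trials
#'
#' For each adverse event, computes the odds ratio of active vs placebo
#' within the weighted IPD trial, divides it by the within-comparator-trial
#' odds ratio, and reports the ratio with a Woolf-type log-scale variance
#' summing the reciprocal cell counts of both 2x2 tables (effective counts
#' for the weighted cells). Anchoring each trial's rate on its own placebo
#' arm adjusts for trial-level differences in AE ascertainment and follow-up.
#'
#' Zero cells receive the classical 0.5 continuity correction applied to all
#' four cells of the affected table, and the correction is flagged. Events
#' whose comparator rates fall at or below the reporting threshold in both
#' comparator arms are flagged non-comparable (published reports omit rarer
#' events). No multiplicity adjustment is applied by default, matching the
#' exploratory character of cross-trial AE screens; `adjust` exposes
#' Bonferroni and Benjamini-Hochberg corrections.
#'
#' @param records IPD patient records with AE flag/onset columns.
#' @param ae_names adverse events to compare.
#' @param weights per-patient matching weights (a numeric vector or a
#'   [maic()] fit), aligned with `records`.
#' @param comparator data.frame with one row per AE: `ae`, `events_active`,
#'   `n_active`, `events_placebo`, `n_placebo` for the aggregate trial.
#' @param cutoffs follow-up cutoffs passed to [censor_ae_followup()];
#'   `NULL` keeps all events.
#' @param threshold comparator reporting threshold (default 0.05).
#' @param adjust multiplicity adjustment for the reported p-values.
#' @return data.frame of class `ae_comparison`: per AE the adjusted odds
#'   ratio, CI, p-value, and flags `continuity_corrected`, `non_comparable`.
#' @export
placebo_adjusted_or <- function(records, ae_names, weights, comparator,
                                cutoffs = NULL, threshold = 0.05,
                                adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(weights, "maic")) weights <- weights$weights
  weights <- rep_len(weights, nrow(records))
  if (!is.null(cutoffs)) {
    records <- records  # counts below re-derive flags from onset cutoffs
    for (ae in ae_names) {
      onset <- records[[paste0("ae_", ae, "_onset")]]
      flag <- records[[paste0("ae_", ae)]]
      if (any(flag & is.na(onset)))
        stop("placebo_adjusted_or: missing onset times for AE '", ae, "'")
      cut <- ifelse(records$arm == "active", cutoffs[["active"]],
                    cutoffs[["placebo"]])
      records[[paste0("ae_", ae)]] <- flag & !is.na(onset) & onset <= cut
    }
  }
  out <- vector("list", length(ae_names))
  for (j in seq_along(ae_names)) {
    ae <- ae_names[j]
    cells_ipd <- .weighted_cells(records, ae, weights)
    ci <- comparator[comparator$ae == ae, , drop = FALSE]
    if (nrow(ci) != 1)
      stop("placebo_adjusted_or: comparator rates missing for AE '", ae, "'")
    tab <- rbind(
      ipd = c(a = cells_ipd["events", "active"],
              b = cells_ipd["n", "active"] - cells_ipd["events", "active"],
              c = cells_ipd["events", "placebo"],
              d = cells_ipd["n", "placebo"] - cells_ipd["events", "placebo"]),
      comp = c(a = ci$events_active, b = ci$n_active - ci$events_active,
               c = ci$events_placebo, d = ci$n_placebo - ci$events_placebo))
    corrected <- FALSE
    for (r in 1:2) if (any(tab[r, ] < 0.5)) { tab[r, ] <- tab[r, ] + 0.5; corrected <- TRUE }
    or_ipd <- (tab["ipd", "a"] * tab["ipd", "d"]) / (tab["ipd", "b"] * tab["ipd", "c"])
    or_comp <- (tab["comp", "a"] * tab["comp", "d"]) / (tab["comp", "b"] * tab["comp", "c"])
    est <- log(or_ipd) - log(or_comp)
    se <- sqrt(sum(1 / tab))
    non_comp <- max(ci$events_active / ci$n_active,
                    ci$events_placebo / ci$n_placebo) <= threshold
    out[[j]] <- data.frame(
      ae = ae, or = exp(est),
      ci_lower = exp(est - .z975 * se), ci_upper = exp(est + .z975 * se),
      p_value = 2 * stats::pnorm(-abs(est / se)), log_se = se,
      or_ipd = or_ipd, or_comparator = or_comp,
      continuity_corrected = corrected, non_comparable = non_comp,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (adjust != "none") res$p_adjusted <- stats::p.adjust(res$p_value, adjust)
  structure(res, kind = "adverse_event",
            class = c("ae_comparison", "data.frame"))
}
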