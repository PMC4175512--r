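.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.as_curve <- function(x, arm, endpoint) {
  if (inherits(x, "digitized_curve")) x
  else read_digitized_curve(x, arm = arm, endpoint = endpoint)
}

.as_at_risk <- function(x) if (inherits(x, "at_risk_table")) x else read_at_risk(x)

.comparison_row <- function(label, endpoint, res) {
  data.frame(comparison = label, endpoint = endpoint, kind = res$kind,
             hr = res$effect, ci_lower = res$ci_lower, ci_upper = res$ci_upper,
             p_value = res$p_value, stringsAsFactors = FALSE)
}

#' Run the full matching-adjusted indirect comparison analysis
#'
#' Executes, in order: eligibility harmonization, pre-matching balance tests,
#' weight estimation, pseudo-IPD reconstruction with verification, the
#' anchored progression-free-survival comparison (before and after
#' matching), unanchored active-vs-active comparisons of overall and
#' progression-free survival, the active-vs-external-control overall-survival
#' comparison with numbers needed to treat, the placebo-arm
#' progression-free-survival negative control, and the placebo-adjusted
#' adverse-event comparison. Any stage error aborts with the stage name;
#' results computed so far are attached to the error condition and, when an
#' output directory is configured, written out.
#'
#' @param config nested list:
#' \describe{
#'   \item{ipd}{patient records data.frame, or path to a CSV readable by
#'     [read_ipd()].}
#'   \item{margins}{a [target_margins()], a data.frame of entries, or a JSON
#'     path for [read_target_margins()].}
#'   \item{eligibility}{list with `excluded_ecog_levels` (default 2) and
#'     `drop_missing` (default TRUE).}
#'   \item{comparator}{list: `n_active`, `n_placebo`; `published_pfs` =
#'     list(hr, ci_lower, ci_upper); `curves` and `at_risk`, named lists
#'     with keys `active.os`, `placebo.os`, `active.pfs`, `placebo.pfs`
#'     (objects or CSV paths); optional `total_events` named alike;
#'     optional `surv_tol` for the reconstruction check (absolute survival
#'     probability; allocation granularity is about 1/n per event, so small
#'     arms warrant a looser value than the 0.005 default); optional `ae`
#'     data.frame for [placebo_adjusted_or()] and `ae_cutoffs`.}
#'   \item{horizons}{months for NNT summaries (default `c(12, 24)`).}
#'   \item{ae_names}{adverse events to compare (default: from `comparator$ae`).}
#'   \item{seed}{integer; fixed before any stage for reproducibility.}
#'   \item{out_dir}{optional output directory; results JSON, balance and
#'     comparison CSVs, Kaplan-Meier coordinates and a timestamped log are
#'     written there.}
#' }
#' @return list of class `maic_analysis`: `eligibility`, `balance`,
#'   `weights` (the [maic()] fit), `reconstruction` (verification reports),
#'   `comparisons` (named list of results), `nnt` (per horizon), `ae`
#'   (when configured), `comparison_table` (flat data.frame), `results`
#'   (plain-list mirror of the numbers, as serialized to JSON).
#' @export
run_analysis <- function(config) {
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  log_lines <- character(0)
  logf <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                      "  ", sprintf(...)))
  }
  partial <- list()
  on_fail <- function(e) {
    attr(e, "partial_results") <- partial
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      try(writeLines(c(log_lines, paste("ERROR:", conditionMessage(e))),
                     file.path(config$out_dir, "log.txt")), silent = TRUE)
    }
    stop(e)
  }
  tryCatch({
    ipd <- .stage("input", if (is.character(config$ipd)) read_ipd(config$ipd)
                           else config$ipd)
    margins <- .stage("input", {
      m <- config$margins
      if (is.character(m)) read_target_margins(m)
      else if (is.data.frame(m)) target_margins(m)
      else m
    })
    comp <- config$comparator
    logf("inputs: %d patients, %d margins, seed %s", nrow(ipd),
         nrow(margins$entries), format(config$seed))

    elig <- .stage("eligibility", apply_eligibility(
      ipd,
      excluded_ecog_levels = config$eligibility$excluded_ecog_levels %||% 2L,
      drop_missing = config$eligibility$drop_missing %||% TRUE))
    partial$eligibility <- elig$exclusions
    sample_ipd <- elig$records
    logf("eligibility: retained %d (excluded: %s)", nrow(sample_ipd),
         paste(names(elig$exclusions), elig$exclusions, collapse = ", "))

    comparator_n <- comp$n_active + comp$n_placebo
    balance <- .stage("balance_tests",
                      balance_tests(sample_ipd, margins, comparator_n))
    partial$balance <- balance

    wfit <- .stage("weighting", maic(sample_ipd, margins))
    partial$weights <- wfit
    logf("weighting: ESS %.1f of %d, max balance error %.1e",
         wfit$ess, wfit$n, wfit$max_balance_error)

    recon <- .stage("reconstruction", {
      out <- list()
      for (key in names(comp$curves)) {
        arm_ep <- strsplit(key, ".", fixed = TRUE)[[1]]
        cv <- .as_curve(comp$curves[[key]], arm_ep[1], arm_ep[2])
        ar <- .as_at_risk(comp$at_risk[[key]])
        out[[key]] <- reconstruct_pseudo_ipd(
          cv, ar, total_events = comp$total_events[[key]],
          surv_tol = comp$surv_tol %||% 0.005)
      }
      out
    })
    verification <- .stage("reconstruction", {
      v <- list()
      if (!is.null(recon$active.pfs) && !is.null(recon$placebo.pfs) &&
          !is.null(comp$published_pfs))
        v$pfs <- verify_reconstruction(
          recon$active.pfs, published_hr = comp$published_pfs$hr,
          comparator = recon$placebo.pfs)
      v
    })
    partial$reconstruction <- verification
    for (nm in names(verification))
      logf("reconstruction check (%s): HR %.3f vs published %.3f [%s]", nm,
           verification[[nm]]$hr, verification[[nm]]$published_hr,
           if (verification[[nm]]$pass) "pass" else "FAIL")

    w <- wfit$weights
    arm_sample <- function(arm, endpoint, weighted = TRUE) {
      idx <- sample_ipd$arm == arm
      survival_sample(sample_ipd[[paste0(endpoint, "_time")]][idx],
                      sample_ipd[[paste0(endpoint, "_event")]][idx],
                      group = arm,
                      weight = if (weighted) w[idx] else 1,
                      endpoint = endpoint)
    }
    both_arms <- function(endpoint, weighted) {
      s <- rbind(arm_sample("active", endpoint, weighted),
                 arm_sample("placebo", endpoint, weighted))
      structure(s, endpoint = endpoint,
                class = c("survival_sample", "data.frame"))
    }

    comparisons <- list()
    pub_pfs <- published_effect(comp$published_pfs$hr,
                                comp$published_pfs$ci_lower,
                                comp$published_pfs$ci_upper,
                                endpoint = "pfs", trial = "comparator")
    comparisons$anchored_pfs_prematch <- .stage("anchored_pfs", {
      fit <- weighted_cox(both_arms("pfs", weighted = FALSE), "placebo")
      fit$endpoint <- "pfs"
      bucher(fit, pub_pfs, check_endpoint = FALSE)
    })
    comparisons$anchored_pfs <- .stage("anchored_pfs", {
      fit <- weighted_cox(both_arms("pfs", weighted = TRUE), "placebo")
      bucher(fit, pub_pfs, check_endpoint = FALSE)
    })
    logf("anchored PFS: HR %.2f pre-match, %.2f post-match",
         comparisons$anchored_pfs_prematch$effect,
         comparisons$anchored_pfs$effect)

    comparisons$unanchored_os <- .stage("unanchored_os",
      unanchored_active_comparison(arm_sample("active", "os"),
                                   recon$active.os))
    comparisons$unanchored_pfs <- .stage("unanchored_pfs",
      unanchored_active_comparison(arm_sample("active", "pfs"),
                                   recon$active.pfs))

    ext <- .stage("external_control",
      external_control_comparison(arm_sample("active", "os"),
                                  recon$placebo.os))
    comparisons$external_control_os <- ext$result
    nnt <- .stage("nnt", lapply(config$horizons %||% c(12, 24), function(h)
      nnt_at(ext$km_active, ext$km_control, h)))
    names(nnt) <- paste0("m", config$horizons %||% c(12, 24))
    for (nm in names(nnt))
      logf("NNT at %g months: %.1f", nnt[[nm]]$horizon, nnt[[nm]]$nnt)

    comparisons$negative_control_pfs <- .stage("negative_control",
      negative_control(arm_sample("placebo", "pfs"), recon$placebo.pfs))
    partial$comparisons <- comparisons

    ae <- NULL
    if (!is.null(comp$ae)) {
      ae <- .stage("ae_comparison", placebo_adjusted_or(
        sample_ipd, ae_names = config$ae_names %||% comp$ae$ae,
        weights = w, comparator = comp$ae, cutoffs = comp$ae_cutoffs))
      partial$ae <- ae
    }

    tab <- rbind(
      .comparison_row("active vs comparator-active (anchored, pre-match)",
                      "pfs", comparisons$anchored_pfs_prematch),
      .comparison_row("active vs comparator-active (anchored)", "pfs",
                      comparisons$anchored_pfs),
      .comparison_row("active vs comparator-active (unanchored)", "os",
                      comparisons$unanchored_os),
      .comparison_row("active vs comparator-active (unanchored)", "pfs",
                      comparisons$unanchored_pfs),
      .comparison_row("active vs external control", "os",
                      comparisons$external_control_os),
      .comparison_row("placebo vs comparator-placebo (negative control)",
                      "pfs", comparisons$negative_control_pfs))

    results <- list(
      n_input = nrow(ipd),
      exclusions = as.list(elig$exclusions),
      n_retained = nrow(sample_ipd),
      ess = wfit$ess,
      max_balance_error = wfit$max_balance_error,
      comparisons = lapply(comparisons, function(r)
        list(kind = r$kind, hr = r$effect, ci_lower = r$ci_lower,
             ci_upper = r$ci_upper, p_value = r$p_value)),
      nnt = lapply(nnt, function(x)
        list(horizon = x$horizon, surv_active = x$surv_active,
             surv_control = x$surv_control, nnt = x$nnt)),
      reconstruction = lapply(verification, function(v)
        list(hr = v$hr, published_hr = v$published_hr, pass = v$pass)),
      ae = if (!is.null(ae))
        lapply(seq_len(nrow(ae)), function(i)
          list(ae = ae$ae[i], or = ae$or[i], ci_lower = ae$ci_lower[i],
               ci_upper = ae$ci_upper[i], p_value = ae$p_value[i],
               non_comparable = ae$non_comparable[i]))
    )

    out <- structure(list(eligibility = elig$exclusions, balance = balance,
                          weights = wfit, reconstruction = verification,
                          comparisons = comparisons, nnt = nnt, ae = ae,
                          km = list(external_active = ext$km_active,
                                    external_control = ext$km_control),
                          comparison_table = tab, results = results),
                     class = "maic_analysis")

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
      utils::write.csv(wfit$balance, file.path(config$out_dir, "balance.csv"),
                       row.names = FALSE)
      utils::write.csv(tab, file.path(config$out_dir, "comparisons.csv"),
                       row.names = FALSE)
      km_out <- rbind(
        data.frame(arm = "active", ext$km_active),
        data.frame(arm = "external_control", ext$km_control))
      utils::write.csv(km_out, file.path(config$out_dir, "km_external.csv"),
                       row.names = FALSE)
      logf("outputs written to %s", config$out_dir)
      writeLines(log_lines, file.path(config$out_dir, "log.txt"))
    }
    out
  }, error = on_fail)
}

#' @export
print.maic_analysis <- function(x, ...) {
  cat("Matching-adjusted indirect comparison analysis\n")
  cat(sprintf("  retained %d patients (excluded: %s); ESS %.1f\n",
              x$weights$n,
              paste(names(x$eligibility), x$eligibility, collapse = ", "),
              x$weights$ess))
  cat("\nComparisons:\n")
  tab <- x$comparison_table
  tab[c("hr", "ci_lower", "ci_upper")] <-
    lapply(tab[c("hr", "ci_lower", "ci_upper")], round, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat("\n")
  for (nm in names(x$nnt)) print(x$nnt[[nm]])
  invisible(x)
}
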