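#' Configuration for a synthetic randomized trial
#'
#' Defines the data-generating law for a two-arm placebo-controlled trial with
#' covariate-dependent proportional hazards on progression-free survival (PFS)
#' and overall survival (OS), progression-triggered crossover on the placebo
#' arm, and administrative censoring at a fixed data cutoff.
#'
#' Event times are exponential conditional on covariates: the simplest law
#' satisfying proportional hazards. Placebo patients who progress before death
#' cross over to active therapy with probability `crossover_probability`,
#' exactly at their progression time; from that moment their death hazard is
#' multiplied by `exp(post_crossover_log_hr_os)`. This piecewise-constant
#' switch is the minimal mechanism producing the intention-to-treat OS
#' contamination that motivates external-control comparisons.
#'
#' @param n_per_arm patients per arm (>= 1).
#' @param covariate_margins named list of baseline margins: `age_median`
#'   (years), and proportions `female`, `ecog0`, `ecog2`, `dx_ge3y`
#'   (time since diagnosis >= 3 years), `sites1`, `sites2` (number of disease
#'   sites; the >=3 level takes the remainder), `distant_mets`, `prior_ssa`,
#'   `prior_chemo`. Categorical covariates are drawn independently; only the
#'   marginals are specified.
#' @param baseline_hazard_pfs,baseline_hazard_os baseline event rates per
#'   month (> 0) for progression and death in a reference patient.
#' @param log_hr_treatment_pfs,log_hr_treatment_os log hazard ratios for
#'   active vs placebo.
#' @param covariate_log_hrs named numeric vector of prognostic log hazard
#'   ratios applied to both endpoints; names must be covariate features
#'   resolvable by [covariate_feature()] (e.g. `ecog0`, `prior_chemo`,
#'   `age_gt64`).
#' @param crossover_probability probability in `[0, 1]` that a placebo patient
#'   who progresses before death crosses over to active therapy.
#' @param post_crossover_log_hr_os log hazard ratio applied to the death
#'   hazard after crossover.
#' @param censor_cutoff_months administrative censoring time (months).
#' @param ae_probs optional named list of adverse-event incidence
#'   probabilities, one entry per AE name, each a vector
#'   `c(active = p, placebo = p)`; onset times are uniform on
#'   `[0, ae_onset_max]` for affected patients.
#' @param ae_onset_max upper bound of the uniform AE onset window (months);
#'   defaults to `censor_cutoff_months`.
#' @param assessment_interval_months optional imaging-assessment interval; if
#'   set, progression components of PFS are rounded up to the next scheduled
#'   assessment. Off by default: no published parameters calibrate it.
#' @param seed integer seed; the same config and seed give byte-identical
#'   output.
#' @return An object of class `trial_config`.
#' @seealso [simulate_trial()], [summarize_as_aggregate()]
#' @export
trial_config <- function(n_per_arm,
                         covariate_margins = list(),
                         baseline_hazard_pfs = 0.15,
                         baseline_hazard_os = 0.028,
                         log_hr_treatment_pfs = 0,
                         log_hr_treatment_os = 0,
                         covariate_log_hrs = numeric(0),
                         crossover_probability = 0,
                         post_crossover_log_hr_os = 0,
                         censor_cutoff_months = 36,
                         ae_probs = NULL,
                         ae_onset_max = NULL,
                         assessment_interval_months = NULL,
                         seed = 1L) {
  defaults <- list(age_median = 58, female = 0.45, ecog0 = 0.65, ecog2 = 0,
                   dx_ge3y = 0.47, sites1 = 0.30, sites2 = 0.35,
                   distant_mets = 0.95, prior_ssa = 0.45, prior_chemo = 0.50)
  margins <- utils::modifyList(defaults, as.list(covariate_margins))
  props <- unlist(margins[setdiff(names(margins), "age_median")])
  if (any(props < 0 | props > 1)) stop("covariate proportions must lie in [0, 1]")
  if (margins$ecog0 + margins$ecog2 > 1)
    stop("ecog0 + ecog2 proportions exceed 1")
  if (margins$sites1 + margins$sites2 > 1)
    stop("sites1 + sites2 proportions exceed 1")
  if (!is.finite(baseline_hazard_pfs) || baseline_hazard_pfs <= 0 ||
      !is.finite(baseline_hazard_os) || baseline_hazard_os <= 0)
    stop("baseline hazard rates must be finite and > 0")
  stopifnot(n_per_arm >= 1,
            crossover_probability >= 0, crossover_probability <= 1,
            censor_cutoff_months > 0)
  if (!all(is.finite(c(log_hr_treatment_pfs, log_hr_treatment_os,
                       post_crossover_log_hr_os, covariate_log_hrs))))
    stop("log hazard ratios must be finite")
  structure(list(n_per_arm = as.integer(n_per_arm),
                 covariate_margins = margins,
                 baseline_hazard_pfs = baseline_hazard_pfs,
                 baseline_hazard_os = baseline_hazard_os,
                 log_hr_treatment_pfs = log_hr_treatment_pfs,
                 log_hr_treatment_os = log_hr_treatment_os,
                 covariate_log_hrs = covariate_log_hrs,
                 crossover_probability = crossover_probability,
                 post_crossover_log_hr_os = post_crossover_log_hr_os,
                 censor_cutoff_months = censor_cutoff_months,
                 ae_probs = ae_probs,
                 ae_onset_max = ae_onset_max %||% censor_cutoff_months,
                 assessment_interval_months = assessment_interval_months,
                 seed = as.integer(seed)),
            class = "trial_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shifted gamma whose median equals the configured median: matching is on
# medians, not means, so the median is the calibrated quantity.
.draw_age <- function(n, median_age, shape = 6, shift = 30) {
  scale <- (median_age - shift) / stats::qgamma(0.5, shape)
  shift + stats::rgamma(n, shape = shape, scale = scale)
}

#' Resolve a named covariate feature from patient records
#'
#' Maps margin/effect names to numeric columns: `age` (years), `age_gt64`,
#' `female`, `ecog0`, `ecog1`, `ecog2`, `dx_ge3y`, `sites1`, `sites2`,
#' `sites3` (>= 3 disease sites), `distant_mets`, `prior_ssa`, `prior_chemo`.
#'
#' @param records patient records as returned by [simulate_trial()].
#' @param name feature name.
#' @return numeric vector, one value per record.
#' @export
covariate_feature <- function(records, name) {
  out <- switch(name,
    age          = records$age,
    age_gt64     = as.numeric(records$age > 64),
    female       = as.numeric(records$sex == "F"),
    ecog0        = as.numeric(records$ecog == 0),
    ecog1        = as.numeric(records$ecog == 1),
    ecog2        = as.numeric(records$ecog == 2),
    dx_ge3y      = as.numeric(records$time_since_dx_ge3y),
    sites1       = as.numeric(records$n_disease_sites == "1"),
    sites2       = as.numeric(records$n_disease_sites == "2"),
    sites3       = as.numeric(records$n_disease_sites == ">=3"),
    distant_mets = as.numeric(records$distant_mets),
    prior_ssa    = as.numeric(records$prior_ssa),
    prior_chemo  = as.numeric(records$prior_chemo),
    stop("unknown covariate feature: ", name)
  )
  out
}

.linear_predictor <- function(records, log_hrs) {
  lp <- rep(0, nrow(records))
  for (nm in names(log_hrs)) lp <- lp + log_hrs[[nm]] * covariate_feature(records, nm)
  lp
}

#' Simulate a two-arm trial with crossover
#'
#' Draws baseline covariates to match the configured margins in expectation,
#' then latent progression and death times from covariate-dependent
#' exponential proportional-hazards models. PFS is the minimum of progression
#' and death. A Bernoulli-selected subset of placebo progressors crosses over
#' at the progression time, after which the death hazard is multiplied by
#' `exp(post_crossover_log_hr_os)`. All times are administratively censored at
#' the configured cutoff.
#'
#' @param config a [trial_config()].
#' @return data.frame of patient records (one row per patient) with columns
#'   `patient_id`, `arm` (`"active"`/`"placebo"`), baseline covariates,
#'   `pfs_time`/`pfs_event`, `os_time`/`os_event`, `crossover_time` (NA when
#'   no observed crossover), and `ae_<name>` / `ae_<name>_onset` columns when
#'   AEs are configured. Attribute `"config"` stores the generating config.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  m <- config$covariate_margins
  n <- 2L * config$n_per_arm
  arm <- rep(c("active", "placebo"), each = config$n_per_arm)

  u <- stats::runif(n)
  ecog <- ifelse(u < m$ecog0, 0L, ifelse(u < m$ecog0 + (1 - m$ecog0 - m$ecog2), 1L, 2L))
  u <- stats::runif(n)
  sites <- ifelse(u < m$sites1, "1", ifelse(u < m$sites1 + m$sites2, "2", ">=3"))
  rec <- data.frame(
    patient_id = seq_len(n),
    arm = arm,
    age = .draw_age(n, m$age_median),
    sex = ifelse(stats::runif(n) < m$female, "F", "M"),
    ecog = ecog,
    time_since_dx_ge3y = stats::runif(n) < m$dx_ge3y,
    n_disease_sites = sites,
    distant_mets = stats::runif(n) < m$distant_mets,
    prior_ssa = stats::runif(n) < m$prior_ssa,
    prior_chemo = stats::runif(n) < m$prior_chemo,
    stringsAsFactors = FALSE
  )

  lp <- .linear_predictor(rec, config$covariate_log_hrs)
  active <- rec$arm == "active"
  rate_prog <- config$baseline_hazard_pfs *
    exp(lp + config$log_hr_treatment_pfs * active)
  rate_death <- config$baseline_hazard_os *
    exp(lp + config$log_hr_treatment_os * active)

  t_prog <- stats::rexp(n, rate_prog)
  t_death <- stats::rexp(n, rate_death)
  if (!is.null(config$assessment_interval_months)) {
    grid <- config$assessment_interval_months
    t_prog <- ceiling(t_prog / grid) * grid
  }

  # crossover: placebo progressors, Bernoulli-selected, switch at progression;
  # residual time to death redrawn from the post-switch hazard (memoryless law)
  progressed <- !active & t_prog < t_death
  sel <- progressed & stats::runif(n) < config$crossover_probability
  t_cross <- ifelse(sel, t_prog, NA_real_)
  if (any(sel)) {
    post_rate <- rate_death[sel] * exp(config$post_crossover_log_hr_os)
    t_death[sel] <- t_prog[sel] + stats::rexp(sum(sel), post_rate)
  }

  pfs_latent <- pmin(t_prog, t_death)
  cutoff <- config$censor_cutoff_months
  rec$pfs_time <- pmin(pfs_latent, cutoff)
  rec$pfs_event <- pfs_latent <= cutoff
  rec$os_time <- pmin(t_death, cutoff)
  rec$os_event <- t_death <= cutoff
  rec$crossover_time <- ifelse(!is.na(t_cross) & t_cross <= cutoff,
                               t_cross, NA_real_)

  if (!is.null(config$ae_probs)) {
    for (ae in names(config$ae_probs)) {
      p <- config$ae_probs[[ae]]
      prob <- ifelse(active, p[["active"]], p[["placebo"]])
      hit <- stats::runif(n) < prob
      rec[[paste0("ae_", ae)]] <- hit
      rec[[paste0("ae_", ae, "_onset")]] <-
        ifelse(hit, stats::runif(n, 0, config$ae_onset_max), NA_real_)
    }
  }
  attr(rec, "config") <- config
  rec
}

#' Collapse simulated records to the published-aggregate view
#'
#' Reduces an IPD trial to what a published report exposes: baseline margins,
#' Kaplan-Meier curves sampled on a time grid, numbers at risk, and hazard
#' ratios with confidence intervals from unweighted proportional-hazards fits.
#' The records themselves remain available to the caller as ground truth for
#' round-trip tests; this function only computes the aggregate view.
#'
#' @param records output of [simulate_trial()].
#' @param config the generating [trial_config()]; defaults to the attribute
#'   stored on `records`.
#' @param grid_step spacing (months) of the digitized-curve time grid.
#' @param at_risk_step spacing (months) of the number-at-risk table.
#' @return list of class `aggregate_summary`: `margins` (a [target_margins()]
#'   built from the sample), `km_curves` and `at_risk` (named
#'   `<arm>.<endpoint>`), `published_hr` (per endpoint: hr, ci_lower,
#'   ci_upper), and `n_per_arm`.
#' @export
summarize_as_aggregate <- function(records, config = attr(records, "config"),
                                   grid_step = 1, at_risk_step = 6) {
  arms <- c("active", "placebo")
  if (any(!table(factor(records$arm, levels = arms))))
    stop("summarize_as_aggregate: empty arm")
  cutoff <- if (!is.null(config)) config$censor_cutoff_months else
    max(records$os_time)

  prop_names <- c("age_gt64", "female", "ecog0", "dx_ge3y", "sites2", "sites3",
                  "distant_mets", "prior_ssa", "prior_chemo")
  entries <- data.frame(
    covariate = c("age", prop_names),
    kind = c("median", rep("proportion", length(prop_names))),
    target = c(stats::median(records$age),
               vapply(prop_names, function(nm)
                 mean(covariate_feature(records, nm)), numeric(1))),
    stringsAsFactors = FALSE
  )
  margins <- target_margins(entries, source = "synthetic aggregate")

  grid <- seq(0, cutoff, by = grid_step)
  risk_times <- seq(0, cutoff, by = at_risk_step)
  km_curves <- list()
  at_risk <- list()
  published_hr <- list()
  for (ep in c("pfs", "os")) {
    tm <- records[[paste0(ep, "_time")]]
    ev <- records[[paste0(ep, "_event")]]
    for (a in arms) {
      idx <- records$arm == a
      fit <- survival::survfit(survival::Surv(tm[idx], ev[idx]) ~ 1)
      s <- summary(fit, times = grid, extend = TRUE)
      km_curves[[paste(a, ep, sep = ".")]] <-
        digitized_curve(time = s$time, survival = s$surv,
                        arm = a, endpoint = ep)
      at_risk[[paste(a, ep, sep = ".")]] <-
        at_risk_table(time = risk_times,
                      n_risk = vapply(risk_times, function(t0)
                        sum(tm[idx] >= t0), numeric(1)))
    }
    if (sum(ev) == 0) next  # degenerate: no events, HR non-estimable
    cx <- survival::coxph(
      survival::Surv(tm, ev) ~ I(arm == "active"), data = records,
      ties = "efron")
    ci <- exp(stats::coef(cx) + c(-1, 1) * .z975 * sqrt(stats::vcov(cx)[1, 1]))
    published_hr[[ep]] <- list(hr = unname(exp(stats::coef(cx))),
                               ci_lower = ci[1], ci_upper = ci[2])
  }
  structure(list(margins = margins, km_curves = km_curves, at_risk = at_risk,
                 published_hr = published_hr,
                 n_per_arm = unname(table(records$arm)[arms])),
            class = "aggregate_summary")
}
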