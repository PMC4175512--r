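#' Read and write patient records as CSV
#'
#' Column dictionary: `patient_id`; `arm` (`active`/`placebo`); `age`
#' (years); `sex` (`F`/`M`); `ecog` (0/1/2); `time_since_dx_ge3y` (logical);
#' `n_disease_sites` (`1`/`2`/`>=3`); `distant_mets`, `prior_ssa`,
#' `prior_chemo` (logical); `pfs_time`, `os_time` (months); `pfs_event`,
#' `os_event` (logical); `crossover_time` (months, empty when absent);
#' optional `ae_<name>` (logical) and `ae_<name>_onset` (months) pairs.
#'
#' @param path CSV file path.
#' @param records patient records.
#' @return `read_ipd` returns the records data.frame.
#' @export
read_ipd <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in grep("^(pfs|os)_event$|^ae_[^_]+$|_ge3y$|^distant_mets$|^prior_",
                   names(rec), value = TRUE))
    rec[[col]] <- as.logical(rec[[col]])
  rec
}

#' @rdname read_ipd
#' @export
write_ipd <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a digitized survival curve from a two-column CSV
#'
#' Expects columns `time_months` and `survival_probability`.
#'
#' @param path CSV file path.
#' @param arm,endpoint labels attached to the curve.
#' @return a [digitized_curve()].
#' @export
read_digitized_curve <- function(path, arm = "", endpoint = "") {
  d <- utils::read.csv(path)
  digitized_curve(d$time_months, d$survival_probability,
                  arm = arm, endpoint = endpoint)
}

#' Read a numbers-at-risk table from CSV
#'
#' Expects columns `time_months` and `n_at_risk`.
#'
#' @param path CSV file path.
#' @return an [at_risk_table()].
#' @export
read_at_risk <- function(path) {
  d <- utils::read.csv(path)
  at_risk_table(d$time_months, d$n_at_risk)
}

#' Read target margins from JSON
#'
#' Expects a JSON object with fields `source` (optional) and `entries`, an
#' array of `{covariate, kind, target}` records.
#'
#' @param path JSON file path.
#' @return a [target_margins()].
#' @export
read_target_margins <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  target_margins(as.data.frame(j$entries), source = j$source %||% "")
}

#' Write an aggregate summary to JSON
#'
#' @param summary an `aggregate_summary` from [summarize_as_aggregate()].
#' @param path JSON file path.
#' @export
write_aggregate_summary <- function(summary, path) {
  out <- list(
    margins = list(source = summary$margins$source,
                   entries = summary$margins$entries),
    km_curves = lapply(summary$km_curves, function(cv)
      list(arm = attr(cv, "arm"), endpoint = attr(cv, "endpoint"),
           time_months = cv$time, survival_probability = cv$survival)),
    at_risk = lapply(summary$at_risk, function(ar)
      list(time_months = ar$time, n_at_risk = ar$n_risk)),
    published_hr = summary$published_hr,
    n_per_arm = as.integer(summary$n_per_arm))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' Thin convenience wrapper: reads the YAML into the nested list expected by
#' [run_analysis()]; file paths inside are resolved relative to the YAML
#' file's directory. Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_analysis_config requires the 'yaml' package")
  cfg <- yaml::yaml.load_file(path)
  cfg$base_dir <- dirname(normalizePath(path))
  cfg
}
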