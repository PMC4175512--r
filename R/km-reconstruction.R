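#' A digitized Kaplan-Meier curve
#'
#' Ordered (time, survival) coordinates read off a published survival figure.
#'
#' @param time months, strictly increasing, starting at 0.
#' @param survival probabilities, starting at 1, nonincreasing, in `[0, 1]`.
#' @param arm,endpoint labels carried through to provenance.
#' @return object of class `digitized_curve` (a data.frame `time`,
#'   `survival` with attributes).
#' @export
digitized_curve <- function(time, survival, arm = "", endpoint = "") {
  stopifnot(length(time) == length(survival), length(time) >= 1)
  if (any(diff(time) <= 0)) stop("digitized_curve: times must be strictly increasing")
  if (abs(survival[1] - 1) > 1e-8 || time[1] != 0)
    stop("digitized_curve: curve must start at (0, 1)")
  if (any(survival < -1e-12 | survival > 1 + 1e-12))
    stop("digitized_curve: survival must lie in [0, 1]")
  if (any(diff(survival) > 1e-12))
    stop("digitized_curve: survival must be nonincreasing")
  structure(data.frame(time = time, survival = pmin(pmax(survival, 0), 1)),
            arm = arm, endpoint = endpoint, class = c("digitized_curve", "data.frame"))
}

#' A published numbers-at-risk table
#'
#' @param time months, strictly increasing, starting at 0.
#' @param n_risk patient counts, nonincreasing; the first entry is the arm
#'   size.
#' @return object of class `at_risk_table`.
#' @export
at_risk_table <- function(time, n_risk) {
  stopifnot(length(time) == length(n_risk), time[1] == 0)
  if (any(diff(time) <= 0)) stop("at_risk_table: times must be strictly increasing")
  if (any(diff(n_risk) > 0)) stop("at_risk_table: counts must be nonincreasing")
  if (any(n_risk < 0)) stop("at_risk_table: counts must be nonnegative")
  structure(data.frame(time = time, n_risk = as.integer(round(n_risk))),
            class = c("at_risk_table", "data.frame"))
}

# allocate d (events) and cen (censorings) over the clicks of one at-risk
# interval, given the censor count for the interval; returns the running
# risk-set and KM bookkeeping needed by the outer loop
.allocate_interval <- function(ks, n_censor, t, S, n_enter, t_start, t_end,
                               last, d, cen, n_hat, KM_hat) {
  lo <- ks[1]
  cen[ks] <- 0L
  cen_t <- numeric(0)
  pre_cen <- 0L
  if (n_censor > 0) {
    cen_t <- t_start + seq_len(n_censor) * (t_end - t_start) / (n_censor + 1)
    idx <- findInterval(cen_t, t[ks])  # 0 = before the interval's first click
    pre_cen <- sum(idx == 0L)
    cen[ks] <- as.integer(tabulate(idx, nbins = length(ks)))
  }
  n_hat[lo] <- max(n_enter - pre_cen, 0L)
  deficit <- 0L
  for (k in ks) {
    if (k > 1 && n_hat[k] == 0L && S[k] < S[k - 1] - 1e-6)
      deficit <- max(deficit, 1L)   # curve still drops but nobody is at risk
    if (k == 1) {
      d[k] <- 0L
    } else if (KM_hat[last] > 0) {
      want <- as.integer(round(n_hat[k] * (1 - S[k] / KM_hat[last])))
      d[k] <- max(0L, min(want, n_hat[k]))
      deficit <- max(deficit, want - n_hat[k])
    } else {
      d[k] <- 0L
    }
    KM_hat[k] <- if (n_hat[k] > 0) KM_hat[last] * (1 - d[k] / n_hat[k]) else KM_hat[last]
    n_hat[k + 1] <- n_hat[k] - d[k] - cen[k]
    if (n_hat[k + 1] < 0) {
      cen[k] <- cen[k] + n_hat[k + 1]   # clamp censorings, never events
      n_hat[k + 1] <- 0L
    }
    if (d[k] != 0) last <- k
  }
  list(d = d, cen = cen, n_hat = n_hat, KM_hat = KM_hat, last = last,
       deficit = deficit, cen_times = cen_t)
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Inverts the product-limit estimator: within each interval between
#' consecutive numbers-at-risk, integer event and censoring counts are
#' allocated so that the recomputed Kaplan-Meier estimate reproduces the
#' digitized survival drops and the published at-risk count at the start of
#' the next interval. Censoring is spread uniformly within intervals (the
#' standard reconstruction convention); events sit exactly at the digitized
#' drop times, preserving the visual steps. If the total event count was
#' published, the censoring allocation of the final interval is chosen to
#' honor it.
#'
#' @param curve a [digitized_curve()].
#' @param at_risk an [at_risk_table()]; its first count is the arm size.
#' @param total_events optional published total number of events.
#' @param surv_tol tolerance (absolute survival probability) for the
#'   recomputed-vs-input check; exceeding it raises a warning.
#' @return object of class `pseudo_ipd`: a data.frame with one row per
#'   patient (`time`, `event`) and attributes `arm`, `endpoint`,
#'   `max_surv_error` (sup-norm of recomputed minus input survival at the
#'   digitized times).
#' @export
reconstruct_pseudo_ipd <- function(curve, at_risk, total_events = NULL,
                                   surv_tol = 0.005) {
  stopifnot(inherits(curve, "digitized_curve"), inherits(at_risk, "at_risk_table"))
  t <- curve$time; S <- curve$survival; K <- length(t)
  trisk <- at_risk$time; nrisk <- as.integer(at_risk$n_risk)
  nrisk <- nrisk[trisk <= t[K]]; trisk <- trisk[trisk <= t[K]]
  I <- length(trisk)
  lower <- vapply(trisk, function(x) which(t >= x - 1e-9)[1], integer(1))
  if (anyNA(lower)) stop("reconstruct_pseudo_ipd: curve does not cover the at-risk interval")

  d <- integer(K); cen <- integer(K); n_hat <- integer(K + 1)
  KM_hat <- rep(1, K); last_i <- 1L; n_hat[1] <- nrisk[1]

  # interval i covers the clicks with times in (trisk[i], trisk[i+1]]: a drop
  # digitized exactly at an at-risk tick belongs to the interval the tick
  # closes, since the published count at the tick excludes those events
  start <- c(1L, lower[-1L] + 1L)
  end <- c(lower[-1L], K)
  cen_keep <- vector("list", I)
  for (i in seq_len(I)) {
    if (start[i] > end[i]) next   # no clicks between consecutive ticks
    ks <- start[i]:end[i]
    final <- i == I
    t_end <- if (final) t[K] else trisk[i + 1]
    if (!final) {
      nc <- as.integer(round(
        nrisk[i] * S[end[i]] / max(S[lower[i]], 1e-12) - nrisk[i + 1]))
      for (iter in 1:100) {
        nc <- max(0L, min(nc, nrisk[i]))
        a <- .allocate_interval(ks, nc, t, S, nrisk[i], trisk[i], t_end,
                                last_i, d, cen, n_hat, KM_hat)
        gap <- a$n_hat[end[i] + 1L] - nrisk[i + 1]
        if (gap == 0 || (gap < 0 && nc == 0)) break
        nc <- nc + gap
      }
    } else {
      # no at-risk anchor beyond the last tick: censoring is zero unless a
      # published total event count pins it down
      run_last <- function(nc) .allocate_interval(
        ks, nc, t, S, nrisk[I], trisk[I], t_end, last_i, d, cen, n_hat, KM_hat)
      a <- run_last(0L)
      if (!is.null(total_events)) {
        best <- a; best_gap <- abs(sum(a$d) - total_events)
        for (nc in seq_len(max(nrisk[I] - 1L, 0L))) {
          cand <- run_last(nc)
          gap <- abs(sum(cand$d) - total_events)
          if (gap < best_gap) { best <- cand; best_gap <- gap }
          if (gap == 0) break
        }
        a <- best
      }
    }
    if (a$deficit >= 1L)
      stop("reconstruct_pseudo_ipd: interval ", i, " starting at t = ",
           trisk[i], " implies more events than the at-risk counts permit")
    d <- a$d; cen <- a$cen; n_hat <- a$n_hat; KM_hat <- a$KM_hat
    last_i <- a$last
    cen_keep[[i]] <- a$cen_times
    if (!final && n_hat[end[i] + 1L] < nrisk[i + 1])
      nrisk[i + 1] <- n_hat[end[i] + 1L]
  }

  # assemble rows: events at drop times, censorings spread in-interval,
  # survivors administratively censored at the end of follow-up
  ev_times <- rep(t, d)
  cen_times <- unlist(cen_keep)
  n_left <- n_hat[K + 1]
  rows <- data.frame(
    time = c(ev_times, cen_times, rep(t[K], n_left)),
    event = c(rep(TRUE, length(ev_times)), rep(FALSE, length(cen_times) + n_left))
  )
  rows <- rows[order(rows$time, -rows$event), , drop = FALSE]
  rownames(rows) <- NULL

  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = rows)
  S_rec <- summary(fit, times = t, extend = TRUE)$surv
  err <- max(abs(S_rec - S))
  if (err > surv_tol)
    warning(sprintf(
      "reconstructed survival deviates from the digitized curve by up to %.3f (> %.3f)",
      err, surv_tol))
  structure(rows, arm = attr(curve, "arm"), endpoint = attr(curve, "endpoint"),
            max_surv_error = err, n_events = sum(d),
            class = c("pseudo_ipd", "data.frame"))
}

#' Verify a reconstruction against published summaries
#'
#' Recomputes the hazard ratio (against a paired comparator arm) and/or the
#' median survival from reconstructed pseudo-IPD and reports absolute and
#' relative deviations from the published values.
#'
#' @param pseudo a [reconstruct_pseudo_ipd()] result.
#' @param published_hr published hazard ratio (`pseudo` arm vs `comparator`),
#'   either a number or a [published_effect()].
#' @param published_median published median survival (months).
#' @param comparator the comparator arm's `pseudo_ipd`; required when
#'   `published_hr` is given.
#' @param hr_tol relative tolerance for the HR check (default 10%).
#' @param median_tol absolute tolerance (months) for the median check
#'   (default 1 month, roughly the digitization grid).
#' @return list of class `reconstruction_check` with recomputed values,
#'   deviations, and a `pass` flag.
#' @export
verify_reconstruction <- function(pseudo, published_hr = NULL,
                                  published_median = NULL, comparator = NULL,
                                  hr_tol = 0.10, median_tol = 1) {
  out <- list(pass = TRUE)
  if (!is.null(published_hr)) {
    if (is.null(comparator))
      stop("verify_reconstruction: HR verification needs the comparator arm")
    if (inherits(published_hr, "published_effect")) published_hr <- published_hr$hr
    dat <- rbind(data.frame(time = pseudo$time, event = pseudo$event, g = 1L),
                 data.frame(time = comparator$time, event = comparator$event, g = 0L))
    cx <- survival::coxph(survival::Surv(time, event) ~ g, data = dat, ties = "efron")
    hr <- unname(exp(stats::coef(cx)))
    out$hr <- hr
    out$published_hr <- published_hr
    out$hr_rel_dev <- abs(hr - published_hr) / published_hr
    out$pass <- out$pass && out$hr_rel_dev <= hr_tol
  }
  if (!is.null(published_median)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             data = as.data.frame(pseudo))
    med <- unname(summary(fit)$table["median"])
    out$median <- med
    out$published_median <- published_median
    out$median_abs_dev <- abs(med - published_median)
    out$pass <- out$pass && isTRUE(out$median_abs_dev <= median_tol)
  }
  structure(out, class = "reconstruction_check")
}

#' @export
print.reconstruction_check <- function(x, ...) {
  cat("Reconstruction verification:", if (x$pass) "PASS" else "FAIL", "\n")
  if (!is.null(x$hr))
    cat(sprintf("  HR %.3f vs published %.3f (rel. dev. %.1f%%)\n",
                x$hr, x$published_hr, 100 * x$hr_rel_dev))
  if (!is.null(x$median))
    cat(sprintf("  median %.1f vs published %.1f months (abs. dev. %.2f)\n",
                x$median, x$published_median, x$median_abs_dev))
  invisible(x)
}
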