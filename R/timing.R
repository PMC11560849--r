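#' Alert-to-onset lead times among true-positive encounters
#'
#' Restricted to encounters with both a fired alert and a sepsis label
#' (whole-encounter true positives), computes the signed lead time
#' `onset_time - alert_time` in minutes: positive when the alert preceded
#' onset, negative when it fired after sepsis had already occurred. Reports
#' the median, the empirical 10th-90th percentile interval (an "80%
#' interval" of the lead-time distribution; inverse-empirical-CDF
#' quantiles, `type = 1`, so the closed interval always brackets at least
#' 80% of the lead times), and the before/at/after split. Ties (lead exactly 0) count with "alert before or
#' at onset".
#'
#' @param firstAlerts data.frame from [extractFiredAlerts()].
#' @param labels data.frame from [labelCohort()].
#' @return object of class `timingSummary`: list with `n_tp`, `lead_times`
#'   (minutes, one per TP encounter), `median_lead`, `interval_80`
#'   (named vector `q10`, `q90`), `fraction_alert_before_onset` (includes
#'   ties), `fraction_alert_after_onset`, and counts `n_before` (> 0),
#'   `n_zero`, `n_after` (< 0). An empty TP set yields `n_tp = 0` with `NA`
#'   statistics.
#' @export
computeLeadTimes <- function(firstAlerts, labels) {
  j <- .alertLabelJoin(firstAlerts, labels)
  tp <- !is.na(j$alert_time) & j$sepsis
  lead <- minutesBetween(j$alert_time[tp], j$onset_time[tp])
  n <- length(lead)
  if (n == 0) {
    out <- list(n_tp = 0L, lead_times = numeric(),
                median_lead = NA_real_,
                interval_80 = c(q10 = NA_real_, q90 = NA_real_),
                fraction_alert_before_onset = NA_real_,
                fraction_alert_after_onset = NA_real_,
                n_before = 0L, n_zero = 0L, n_after = 0L)
  } else {
    out <- list(
      n_tp = n, lead_times = lead,
      median_lead = median(lead),
      interval_80 = c(q10 = quantile(lead, 0.1, type = 1, names = FALSE),
                      q90 = quantile(lead, 0.9, type = 1, names = FALSE)),
      fraction_alert_before_onset = mean(lead >= 0),
      fraction_alert_after_onset = mean(lead < 0),
      n_before = sum(lead > 0), n_zero = sum(lead == 0),
      n_after = sum(lead < 0))
  }
  structure(out, class = "timingSummary")
}

#' @export
print.timingSummary <- function(x, ...) {
  cat("Lead-time summary over", x$n_tp, "true-positive encounters\n")
  if (x$n_tp > 0) {
    cat(sprintf("  median lead: %.0f min (80%% interval %.0f to %.0f min)\n",
                x$median_lead, x$interval_80["q10"], x$interval_80["q90"]))
    cat(sprintf("  alert before/at onset: %.1f%%   after onset: %.1f%%\n",
                100 * x$fraction_alert_before_onset,
                100 * x$fraction_alert_after_onset))
  }
  invisible(x)
}

#' Binned lead-time histogram
#'
#' Counts of lead times in fixed-width bins (default 15 minutes), suitable
#' for CSV export and plotting. Bins are half-open `[start, end)` and
#' aligned to multiples of `binMinutes`.
#'
#' @param timing a `timingSummary` from [computeLeadTimes()].
#' @param binMinutes bin width in minutes.
#' @return data.frame `bin_start`, `bin_end` (minutes), `count`.
#' @export
leadTimeHistogram <- function(timing, binMinutes = 15) {
  stopifnot(inherits(timing, "timingSummary"))
  lead <- timing$lead_times
  if (!length(lead))
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  b <- floor(lead / binMinutes)
  tab <- table(factor(b, levels = seq(min(b), max(b))))
  data.frame(bin_start = as.numeric(names(tab)) * binMinutes,
             bin_end = (as.numeric(names(tab)) + 1) * binMinutes,
             count = as.integer(tab))
}
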