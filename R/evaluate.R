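#' First fired alert per encounter
#'
#' An alert event counts as *fired* (shown to a clinician as an interruptive
#' advisory) only when the model score reached the alerting threshold AND
#' the provider viewed the chart. Sub-threshold score events and un-viewed
#' events are ignored. Returns the earliest fired-alert time per encounter;
#' encounters with no fired alert are absent from the result.
#'
#' @param alertEvents data.frame of alert events (`encounter_id`,
#'   `timestamp`, `model_score`, `chart_viewed`), e.g. `alerts(cohort)`.
#' @param threshold alerting threshold on the model score (default 6, the
#'   vendor-recommended production setting).
#' @return data.frame `encounter_id`, `alert_time` (POSIXct), one row per
#'   alerted encounter.
#' @export
extractFiredAlerts <- function(alertEvents, threshold = 6) {
  ae <- as.data.frame(alertEvents)
  if (!nrow(ae))
    return(data.frame(encounter_id = character(), alert_time = .emptyTs()))
  fired <- ae[!is.na(ae$model_score) & ae$model_score >= threshold &
                ae$chart_viewed %in% TRUE, , drop = FALSE]
  if (!nrow(fired))
    return(data.frame(encounter_id = character(), alert_time = .emptyTs()))
  dt <- data.table::as.data.table(fired)
  out <- dt[, list(alert_time = min(timestamp)), by = "encounter_id"]
  data.table::setorder(out, encounter_id)
  as.data.frame(out)
}

# join first alerts onto labels; every alerted encounter must be labelled
.alertLabelJoin <- function(firstAlerts, labels) {
  if (anyDuplicated(labels$encounter_id))
    stop("labels must contain one row per encounter", call. = FALSE)
  unknown <- setdiff(firstAlerts$encounter_id, labels$encounter_id)
  if (length(unknown))
    stop("alerts reference unlabelled encounter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  i <- match(labels$encounter_id, firstAlerts$encounter_id)
  alert_time <- firstAlerts$alert_time[i]
  data.frame(labels, alert_time = alert_time)
}

#' Windowed confusion matrix for alert-based sepsis prediction
#'
#' Classifies each encounter against the first fired alert with a one-sided
#' forward window: a true positive requires sepsis onset within
#' `[alert_time, alert_time + windowHours]` (closed at both ends, so an
#' onset exactly at the horizon counts). Alerted encounters whose onset
#' falls outside the window are counted as false positives together with
#' alerted non-sepsis encounters; un-alerted encounters split into false
#' negatives (sepsis) and true negatives (no sepsis). This reclassification
#' of out-of-window sepsis onto the "not sepsis" side is what the windowed
#' column totals of an alert-validation table imply.
#'
#' @param firstAlerts data.frame from [extractFiredAlerts()].
#' @param labels data.frame from [labelCohort()].
#' @param windowHours forward horizon in hours (default 6).
#' @return a [ConfusionMatrix-class] with `mode = "windowed"`.
#' @export
windowedConfusion <- function(firstAlerts, labels, windowHours = 6) {
  j <- .alertLabelJoin(firstAlerts, labels)
  alerted <- !is.na(j$alert_time)
  inWindow <- alerted & j$sepsis & !is.na(j$onset_time) &
    j$onset_time >= j$alert_time &
    minutesBetween(j$alert_time, j$onset_time) <= windowHours * 60
  ConfusionMatrix(tp = sum(inWindow),
                  fp = sum(alerted & !inWindow),
                  fn = sum(!alerted & j$sepsis),
                  tn = sum(!alerted & !j$sepsis),
                  mode = "windowed", windowHours = windowHours)
}

#' Whole-encounter confusion matrix
#'
#' As [windowedConfusion()] but with the window removed: a true positive is
#' any alerted encounter that met the sepsis phenotype at any time,
#' regardless of whether the alert preceded or followed onset.
#'
#' @inheritParams windowedConfusion
#' @return a [ConfusionMatrix-class] with `mode = "encounter"`.
#' @export
encounterConfusion <- function(firstAlerts, labels) {
  j <- .alertLabelJoin(firstAlerts, labels)
  alerted <- !is.na(j$alert_time)
  ConfusionMatrix(tp = sum(alerted & j$sepsis),
                  fp = sum(alerted & !j$sepsis),
                  fn = sum(!alerted & j$sepsis),
                  tn = sum(!alerted & !j$sepsis),
                  mode = "encounter", windowHours = Inf)
}

# Wilson score interval for a binomial proportion
.wilsonCI <- function(x, n, level = 0.95) {
  if (is.na(x) || is.na(n) || n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each with
#' a Wilson score confidence interval. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param ciLevel confidence level for the Wilson intervals (default 0.95).
#' @return data.frame with columns `metric`, `estimate`, `lower`, `upper`
#'   (fractions in `[0, 1]`).
#' @export
#' @examples
#' diagnosticMetrics(ConfusionMatrix(550, 6633, 3180, 135522))
diagnosticMetrics <- function(cm, ciLevel = 0.95) {
  stopifnot(is(cm, "ConfusionMatrix"))
  num <- c(sensitivity = cm@tp, specificity = cm@tn,
           ppv = cm@tp, npv = cm@tn)
  den <- c(sensitivity = cm@tp + cm@fn, specificity = cm@tn + cm@fp,
           ppv = cm@tp + cm@fp, npv = cm@tn + cm@fn)
  est <- ifelse(den > 0, num / den, NA_real_)
  ci <- t(mapply(function(x, n) if (n > 0) .wilsonCI(x, n, ciLevel)
                 else c(NA_real_, NA_real_), num, den))
  out <- data.frame(metric = names(num), estimate = unname(est),
                    lower = unname(ci[, 1]), upper = unname(ci[, 2]))
  rownames(out) <- NULL
  out
}

#' Full alert evaluation: both matrices and their metrics
#'
#' Convenience wrapper running [extractFiredAlerts()],
#' [windowedConfusion()] and [encounterConfusion()] and asserting the
#' structural identity that both matrices share their FN and TN cells
#' (both depend only on the un-alerted encounters).
#'
#' @param labels data.frame from [labelCohort()].
#' @param alertEvents raw alert events, e.g. `alerts(cohort)`.
#' @param windowHours forward horizon in hours (default 6).
#' @param threshold alerting threshold (default 6).
#' @param ciLevel confidence level for metric CIs.
#' @return list with elements `windowed`, `encounter` (ConfusionMatrix),
#'   `windowedMetrics`, `encounterMetrics` (data.frames).
#' @export
evaluateAlerts <- function(labels, alertEvents, windowHours = 6,
                           threshold = 6, ciLevel = 0.95) {
  fa <- extractFiredAlerts(alertEvents, threshold = threshold)
  w <- windowedConfusion(fa, labels, windowHours = windowHours)
  e <- encounterConfusion(fa, labels)
  stopifnot(w@fn == e@fn, w@tn == e@tn)
  list(windowed = w, encounter = e,
       windowedMetrics = diagnosticMetrics(w, ciLevel),
       encounterMetrics = diagnosticMetrics(e, ciLevel))
}
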