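#' Monte-Carlo random-alert null model
#'
#' Benchmarks the alerting system against chance: in each replicate every
#' encounter independently receives a pseudo-alert with probability
#' `alertPrevalence` at a time drawn uniformly over its stay, and the same
#' confusion-matrix machinery used for the real alerts is applied. The
#' resulting metric distribution is the expected performance of an
#' uninformative alert fired at the observed alert rate.
#'
#' With `firing = "per_interval"` each 15-minute grid interval instead fires
#' independently with probability `alertPrevalence` and the first firing
#' interval (if any) provides the alert time — an alternative null whose
#' per-encounter alert probability grows with length of stay.
#'
#' @param encounterTable data.frame of encounters (needs `encounter_id`,
#'   `ed_arrival`, `discharge`), e.g. `encounters(cohort)`.
#' @param labels data.frame from [labelCohort()].
#' @param alertPrevalence firing probability (per encounter, or per interval
#'   under `firing = "per_interval"`); in `(0, 1)`.
#' @param nReps number of Monte-Carlo replicates (default 500).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param windowHours horizon for windowed mode.
#' @param mode `"windowed"` or `"encounter"` confusion-matrix construction.
#' @param firing `"per_encounter"` (default) or `"per_interval"`.
#' @param stepMinutes interval length for `"per_interval"` firing.
#' @return object of class `nullAlertResult`: list with `reps` (one row per
#'   replicate: counts and the four metrics), `summary` (per-metric mean and
#'   10th/50th/90th percentiles), and the call parameters.
#' @export
#' @examples
#' sim <- simulateCohort(scenarioConfig(nEncounters = 200, seed = 3))
#' labels <- labelCohort(computeSofaSeries(sim$cohort), orders(sim$cohort))
#' simulateRandomAlerts(encounters(sim$cohort), labels,
#'                      alertPrevalence = 0.05, nReps = 50, seed = 9)
simulateRandomAlerts <- function(encounterTable, labels, alertPrevalence,
                                 nReps = 500, seed = 1, windowHours = 6,
                                 mode = c("windowed", "encounter"),
                                 firing = c("per_encounter", "per_interval"),
                                 stepMinutes = 15) {
  mode <- match.arg(mode)
  firing <- match.arg(firing)
  stopifnot(alertPrevalence >= 0, alertPrevalence <= 1, nReps >= 1)
  enc <- as.data.frame(encounterTable)
  n <- nrow(enc)
  losMin <- minutesBetween(enc$ed_arrival, enc$discharge)
  nInt <- floor(losMin / stepMinutes) + 1L
  reps <- withSeed(seed, {
    out <- vector("list", nReps)
    for (r in seq_len(nReps)) {
      if (firing == "per_encounter") {
        hit <- runif(n) < alertPrevalence
        at <- enc$ed_arrival + runif(n) * losMin * 60
      } else {
        # geometric first-success over the encounter's intervals
        g <- stats::rgeom(n, max(alertPrevalence, .Machine$double.eps)) + 1L
        hit <- alertPrevalence > 0 & g <= nInt
        at <- enc$ed_arrival + (g - 1L) * stepMinutes * 60
      }
      fa <- data.frame(encounter_id = enc$encounter_id[hit],
                       alert_time = at[hit])
      cm <- if (mode == "windowed")
        windowedConfusion(fa, labels, windowHours = windowHours)
      else encounterConfusion(fa, labels)
      m <- diagnosticMetrics(cm)
      out[[r]] <- data.frame(rep = r, tp = cm@tp, fp = cm@fp, fn = cm@fn,
                             tn = cm@tn,
                             sensitivity = m$estimate[m$metric == "sensitivity"],
                             specificity = m$estimate[m$metric == "specificity"],
                             ppv = m$estimate[m$metric == "ppv"],
                             npv = m$estimate[m$metric == "npv"])
    }
    do.call(rbind, out)
  })
  metrics <- c("sensitivity", "specificity", "ppv", "npv")
  summ <- do.call(rbind, lapply(metrics, function(mn) {
    v <- reps[[mn]]
    data.frame(metric = mn, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE),
               q10 = quantile(v, 0.1, na.rm = TRUE, names = FALSE),
               q50 = quantile(v, 0.5, na.rm = TRUE, names = FALSE),
               q90 = quantile(v, 0.9, na.rm = TRUE, names = FALSE))
  }))
  structure(list(reps = reps, summary = summ, nReps = nReps, seed = seed,
                 alertPrevalence = alertPrevalence, mode = mode,
                 firing = firing, windowHours = windowHours),
            class = "nullAlertResult")
}

#' @export
print.nullAlertResult <- function(x, ...) {
  cat(sprintf("Random-alert null: %d replicates, prevalence %.4g, %s mode (%s firing)\n",
              x$nReps, x$alertPrevalence, x$mode, x$firing))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Chance-adjust a sensitivity against the random-alert null
#'
#' Subtracts the null-model sensitivity from the observed model
#' sensitivity, floored at zero: the sensitivity attributable to the model
#' beyond random firing at the same alert rate.
#'
#' @param modelSensitivity,nullSensitivity fractions in `[0, 1]`.
#' @return adjusted sensitivity, a fraction in `[0, 1]`.
#' @export
#' @examples
#' adjustForRandomness(0.147, 0.0127)  # 0.1343
adjustForRandomness <- function(modelSensitivity, nullSensitivity) {
  stopifnot(all(modelSensitivity >= 0 & modelSensitivity <= 1),
            all(nullSensitivity >= 0 & nullSensitivity <= 1))
  pmax(0, modelSensitivity - nullSensitivity)
}
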