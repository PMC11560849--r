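#' Scenario configuration for synthetic cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults reproduce the joint alert/onset structure of a large two-site
#' county-ED cohort: 3.7% sepsis prevalence, 4.9% fired-alert prevalence, a
#' 2253/5433 alert rate among sepsis encounters, and a two-sided lead-time
#' mixture in which half of alerted sepsis encounters are alerted only
#' after onset and 550/2253 have onset within the 6-hour forward window of
#' the alert. The alert rate among non-sepsis encounters is solved from the
#' marginal alert prevalence, so the configuration spans both reported
#' marginals and the window-conditional count.
#'
#' `leadTimeDistribution` families (`lead = onset - alert`, minutes;
#' positive = alert first):
#' * `point_mass`: all leads equal `params$at`.
#' * `uniform`: leads uniform on `[params$min, params$max]`.
#' * `two_sided_mixture` (default): three uniform components --- alert
#'   after onset on `params$afterRange`, alert within the forward window on
#'   `params$windowRange`, and early alerts beyond the window on
#'   `params$lateRange` --- mixed with `params$weights`.
#'
#' @param nEncounters number of encounters to generate.
#' @param sepsisPrevalence marginal probability an encounter meets the
#'   sepsis phenotype (default 0.037).
#' @param alertPrevalence marginal probability of a fired alert (default
#'   0.049).
#' @param pAlertGivenSepsis alert probability among sepsis encounters
#'   (default 2253/5433).
#' @param leadTimeDistribution list `family`/`params`, see Details.
#' @param windowHours forward evaluation horizon (hours, default 6).
#' @param demographics list of category proportions for `sex`, `age_band`,
#'   `race`, and per-comorbidity prevalences; defaults to the marginals of
#'   a large county-ED population. Each proportion vector must sum to 1.
#' @param orderNoiseFraction fraction of non-sepsis encounters that still
#'   receive blood-culture and antibiotic orders (order noise; default
#'   0.2). Their SOFA stays flat, so the order requirement alone never
#'   creates a label.
#' @param decoyAlertRate rate of decoy alert events (sub-threshold score,
#'   or unviewed chart) that downstream extraction must ignore.
#' @param losMeanLogMinutes,losSdLog log-normal length-of-stay parameters
#'   for non-sepsis encounters (minutes; default meanlog `log(420)`, sdlog
#'   0.9).
#' @param sepsisTailMeanLogMinutes,sepsisTailSdLog log-normal tail of stay
#'   after the later of onset and alert for sepsis encounters.
#' @param studyStart first possible arrival date (UTC).
#' @param studyDays arrivals are uniform over this many days.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return validated list of class `scenarioConfig`.
#' @export
scenarioConfig <- function(nEncounters,
                           sepsisPrevalence = 0.037,
                           alertPrevalence = 0.049,
                           pAlertGivenSepsis = 2253 / 5433,
                           leadTimeDistribution = defaultLeadTimeDistribution(),
                           windowHours = 6,
                           demographics = defaultDemographics(),
                           orderNoiseFraction = 0.2,
                           decoyAlertRate = 0.05,
                           losMeanLogMinutes = log(420), losSdLog = 0.9,
                           sepsisTailMeanLogMinutes = log(720),
                           sepsisTailSdLog = 0.6,
                           studyStart = "2023-01-01", studyDays = 364,
                           seed = 1) {
  cfg <- list(nEncounters = as.integer(nEncounters),
              sepsisPrevalence = sepsisPrevalence,
              alertPrevalence = alertPrevalence,
              pAlertGivenSepsis = pAlertGivenSepsis,
              leadTimeDistribution = leadTimeDistribution,
              windowHours = windowHours, demographics = demographics,
              orderNoiseFraction = orderNoiseFraction,
              decoyAlertRate = decoyAlertRate,
              losMeanLogMinutes = losMeanLogMinutes, losSdLog = losSdLog,
              sepsisTailMeanLogMinutes = sepsisTailMeanLogMinutes,
              sepsisTailSdLog = sepsisTailSdLog,
              studyStart = studyStart, studyDays = studyDays,
              seed = as.integer(seed))
  frac <- c(sepsisPrevalence, alertPrevalence, pAlertGivenSepsis,
            orderNoiseFraction, decoyAlertRate)
  if (any(frac < 0 | frac > 1))
    stop("prevalences and fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$nEncounters < 1) stop("nEncounters must be >= 1", call. = FALSE)
  for (nm in c("sex", "age_band", "race")) {
    p <- demographics[[nm]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-9)
      stop("demographics$", nm, " proportions must sum to 1", call. = FALSE)
  }
  cfg$pAlertGivenNonSepsis <- .solveNonSepsisAlertRate(
    sepsisPrevalence, alertPrevalence, pAlertGivenSepsis)
  if (!cfg$leadTimeDistribution$family %in%
      c("point_mass", "uniform", "two_sided_mixture"))
    stop("unknown lead-time family: ", cfg$leadTimeDistribution$family,
         call. = FALSE)
  structure(cfg, class = "scenarioConfig")
}

# alert rate among non-sepsis encounters implied by the marginals
.solveNonSepsisAlertRate <- function(pSepsis, pAlert, pAlertGivenSepsis) {
  if (pSepsis >= 1) {
    if (pAlertGivenSepsis < pAlert - 1e-12)
      stop("infeasible joint structure: p(alert|sepsis) < alert prevalence ",
           "with sepsis prevalence 1", call. = FALSE)
    return(0)
  }
  p <- (pAlert - pAlertGivenSepsis * pSepsis) / (1 - pSepsis)
  if (p < -1e-12 || p > 1 + 1e-12)
    stop(sprintf(paste0("infeasible joint structure: implied non-sepsis ",
                        "alert rate %.4f outside [0, 1]"), p), call. = FALSE)
  min(max(p, 0), 1)
}

#' @rdname scenarioConfig
#' @export
defaultLeadTimeDistribution <- function() {
  list(family = "two_sided_mixture",
       params = list(weights = c(after = 1126, window = 550, late = 577) / 2253,
                     afterRange = c(-502.5, 0),
                     windowRange = c(0, 360),
                     lateRange = c(360, 951)))
}

#' @rdname scenarioConfig
#' @export
defaultDemographics <- function() {
  list(
    sex = c(female = 66173, male = 79712) / 145885,
    age_band = c(`18-44` = 66384, `45-64` = 55678, `65+` = 23823) / 145885,
    race = c(Asian = 1384, Black = 43837, Hispanic = 80913,
             White = 14979, Other = 4754) / 145867,
    comorbidities = c(diabetes = 33612, hyperlipidemia = 35962,
                      chronic_kidney_disease = 1803, cabg = 3947,
                      pvd = 3842, stroke = 4265) / 145885
  )
}

#' Read a scenario configuration from a YAML file
#'
#' Keys mirror the arguments of [scenarioConfig()].
#'
#' @param path YAML file.
#' @return a `scenarioConfig`.
#' @export
readScenarioConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("leadTimeDistribution", "demographics"))
    if (!is.null(raw[[nm]]))
      raw[[nm]] <- rapply(raw[[nm]], unlist, how = "replace")
  if (!is.null(raw$demographics))
    raw$demographics <- lapply(raw$demographics, unlist)
  do.call(scenarioConfig, raw)
}

.drawLead <- function(dist, n) {
  p <- dist$params
  switch(dist$family,
    point_mass = rep(as.numeric(p$at), n),
    uniform = runif(n, p$min, p$max),
    two_sided_mixture = {
      ranges <- rbind(p$afterRange, p$windowRange, p$lateRange)
      comp <- sample.int(3L, n, replace = TRUE, prob = p$weights)
      runif(n, ranges[comp, 1], ranges[comp, 2])
    })
}

.snapSec <- function(t) as.POSIXct(round(as.numeric(t)),
                                   origin = "1970-01-01", tz = "UTC")

#' Plant the cohort skeleton: encounters plus ground truth
#'
#' Draws per-encounter demographics, arrival times, sepsis status
#' (Bernoulli at the configured prevalence), alert status (Bernoulli at
#' `pAlertGivenSepsis` among sepsis encounters and at the solved
#' complementary rate otherwise), signed alert-to-onset lead times from the
#' configured distribution, and onset times on the 15-minute grid relative
#' to arrival. Discharge is placed after the later of onset and alert plus
#' a log-normal tail, so every planted time is inside its encounter.
#'
#' @param config a [scenarioConfig()].
#' @return list with `encounterTable` (the encounters data.frame) and
#'   `truth` (data.frame `encounter_id`, `sepsis`, `onset_time`,
#'   `alert_time`; onset present iff sepsis, alert present iff an alert was
#'   planted).
#' @export
plantSkeleton <- function(config) {
  stopifnot(inherits(config, "scenarioConfig"))
  n <- config$nEncounters
  dgr <- config$demographics
  withSeed(config$seed, {
    sex <- sample(names(dgr$sex), n, replace = TRUE, prob = dgr$sex)
    band <- sample(names(dgr$age_band), n, replace = TRUE,
                   prob = dgr$age_band)
    age <- ifelse(band == "18-44", sample(18:44, n, replace = TRUE),
           ifelse(band == "45-64", sample(45:64, n, replace = TRUE),
                  sample(65:95, n, replace = TRUE)))
    race <- sample(names(dgr$race), n, replace = TRUE, prob = dgr$race)
    flags <- lapply(dgr$comorbidities, function(p) runif(n) < p)

    arrival <- as.POSIXct(config$studyStart, tz = "UTC") +
      floor(runif(n, 0, config$studyDays * 1440)) * 60

    sepsis <- runif(n) < config$sepsisPrevalence
    pAlert <- ifelse(sepsis, config$pAlertGivenSepsis,
                     config$pAlertGivenNonSepsis)
    alerted <- runif(n) < pAlert

    lead <- rep(NA_real_, n)
    iSA <- which(sepsis & alerted)
    lead[iSA] <- .drawLead(config$leadTimeDistribution, length(iSA))

    # onset on the 15-min grid, late enough that a preceding alert fits
    leadPos <- ifelse(is.na(lead), 0, pmax(lead, 0))
    onsetOffset <- 15 * ceiling((leadPos + runif(n, 15, 720)) / 15)
    onset <- .emptyTs()[rep(1L, n)]
    onset[sepsis] <- arrival[sepsis] + onsetOffset[sepsis] * 60

    alert <- .emptyTs()[rep(1L, n)]
    alert[iSA] <- .snapSec(onset[iSA] - lead[iSA] * 60)

    # discharge after everything planted, with a log-normal tail
    lastEvent <- arrival
    lastEvent[sepsis] <- onset[sepsis]
    ia <- which(!is.na(alert) & alert > lastEvent)
    lastEvent[ia] <- alert[ia]
    tail <- ifelse(sepsis,
                   rlnorm(n, config$sepsisTailMeanLogMinutes,
                          config$sepsisTailSdLog),
                   pmax(60, rlnorm(n, config$losMeanLogMinutes,
                                   config$losSdLog)))
    discharge <- .snapSec(lastEvent + pmax(round(tail), 30) * 60)

    # alerts for non-sepsis encounters: uniform over the stay
    iNA <- which(!sepsis & alerted)
    alert[iNA] <- .snapSec(arrival[iNA] + runif(length(iNA)) *
                             as.numeric(discharge[iNA] - arrival[iNA],
                                        units = "secs"))

    id <- sprintf("E%06d", seq_len(n))
    encTab <- data.frame(encounter_id = id, sex = sex,
                         age_years = as.integer(age), race = race)
    for (cm in .COMORBIDITIES) encTab[[cm]] <- flags[[cm]]
    encTab$ed_arrival <- arrival
    encTab$discharge <- discharge
    truth <- data.frame(encounter_id = id, sepsis = sepsis,
                        onset_time = onset, alert_time = alert)
    list(encounterTable = encTab, truth = truth)
  })
}

# organ-derangement step profiles applied at onset; each adds >= 2 SOFA
# points over the normal baseline
.ONSET_PROFILES <- list(
  list(platelets = 90),                      # coagulation +2
  list(bilirubin = 2.5),                     # liver +2
  list(creatinine = 2.6),                    # renal +2
  list(gcs = 11),                            # cns +2
  list(map = 62, norepinephrine = 0.05),     # cardiovascular +3
  list(platelets = 120, bilirubin = 1.5)     # coagulation +1, liver +1
)

.NORMAL_BASELINE <- c(pf_ratio = 450, platelets = 250, bilirubin = 0.5,
                      map = 85, gcs = 15, creatinine = 0.8,
                      urine_output_24h = 1500, ventilated = 0)

#' Synthesise observations and orders realising the planted truth
#'
#' Every encounter gets a full panel of normal observations at arrival
#' (total SOFA 0, nothing imputed). Sepsis encounters additionally get a
#' randomly chosen piecewise-constant organ-failure step profile at the
#' planted onset time that raises the total SOFA by >= 2 exactly there, so
#' the phenotype's first two-point crossing recovers the planted onset.
#' Blood-culture and antibiotic orders are emitted at onset for every
#' sepsis encounter; a configurable fraction of non-sepsis encounters also
#' receives both orders (order noise) while keeping a flat SOFA of 0, so
#' the order requirement alone never produces a label.
#'
#' @param truth ground-truth data.frame from [plantSkeleton()].
#' @param encounterTable encounters data.frame from [plantSkeleton()].
#' @param orderNoiseFraction fraction of non-sepsis encounters receiving
#'   both orders.
#' @param seed integer seed.
#' @return list with `observations` and `orderEvents` data.frames.
#' @export
synthesizeObservations <- function(truth, encounterTable,
                                   orderNoiseFraction = 0.2, seed = 1) {
  enc <- as.data.frame(encounterTable)
  tr <- as.data.frame(truth)
  stopifnot(identical(tr$encounter_id, enc$encounter_id))
  iS <- which(tr$sepsis)
  bad <- iS[is.na(tr$onset_time[iS]) |
              tr$onset_time[iS] < enc$ed_arrival[iS] |
              tr$onset_time[iS] > enc$discharge[iS]]
  if (length(bad))
    stop("planted onset outside encounter bounds for: ",
         paste(tr$encounter_id[bad], collapse = ", "), call. = FALSE)
  n <- nrow(enc)
  base <- data.frame(
    encounter_id = rep(enc$encounter_id, each = length(.NORMAL_BASELINE)),
    timestamp = rep(enc$ed_arrival, each = length(.NORMAL_BASELINE)),
    kind = rep(names(.NORMAL_BASELINE), n),
    value = rep(unname(.NORMAL_BASELINE), n))
  withSeed(seed, {
    prof <- sample.int(length(.ONSET_PROFILES), length(iS), replace = TRUE)
    onsetObs <- do.call(rbind, lapply(seq_along(iS), function(k) {
      p <- .ONSET_PROFILES[[prof[k]]]
      data.frame(encounter_id = tr$encounter_id[iS[k]],
                 timestamp = tr$onset_time[iS[k]],
                 kind = names(p), value = unname(unlist(p)))
    }))
    ordersSepsis <- data.frame(
      encounter_id = rep(tr$encounter_id[iS], each = 2L),
      timestamp = rep(tr$onset_time[iS], each = 2L),
      kind = rep(.ORDER_KINDS, length(iS)))
    iN <- which(!tr$sepsis)
    iNoise <- iN[runif(length(iN)) < orderNoiseFraction]
    tNoise <- .snapSec(enc$ed_arrival[iNoise] + runif(length(iNoise)) *
                         as.numeric(enc$discharge[iNoise] -
                                      enc$ed_arrival[iNoise], units = "secs"))
    ordersNoise <- data.frame(
      encounter_id = rep(enc$encounter_id[iNoise], each = 2L),
      timestamp = rep(tNoise, each = 2L),
      kind = rep(.ORDER_KINDS, length(iNoise)))
    obs <- rbind(base, onsetObs)
    ords <- rbind(ordersSepsis, ordersNoise)
    rownames(obs) <- rownames(ords) <- NULL
    list(observations = obs, orderEvents = ords)
  })
}

#' Synthesise alert events realising the planted alert times
#'
#' Emits one fired alert (model score at or above the threshold, chart
#' viewed) at each planted alert time, plus decoy events --- sub-threshold
#' scores with the chart viewed, and above-threshold scores without a chart
#' view --- that the fired-alert extraction must ignore.
#'
#' @param truth ground-truth data.frame from [plantSkeleton()].
#' @param encounterTable encounters data.frame.
#' @param decoyAlertRate per-encounter probability of each decoy type.
#' @param threshold alerting threshold (default 6).
#' @param seed integer seed.
#' @return alerts data.frame (`encounter_id`, `timestamp`, `model_score`,
#'   `chart_viewed`).
#' @export
synthesizeAlerts <- function(truth, encounterTable, decoyAlertRate = 0.05,
                             threshold = 6, seed = 1) {
  enc <- as.data.frame(encounterTable)
  tr <- as.data.frame(truth)
  withSeed(seed, {
    iA <- which(!is.na(tr$alert_time))
    fired <- data.frame(
      encounter_id = tr$encounter_id[iA],
      timestamp = tr$alert_time[iA],
      model_score = as.integer(sample(threshold:10, length(iA),
                                      replace = TRUE)),
      chart_viewed = rep(TRUE, length(iA)))
    decoy <- function(subThreshold) {
      i <- which(runif(nrow(enc)) < decoyAlertRate)
      t <- .snapSec(enc$ed_arrival[i] + runif(length(i)) *
                      as.numeric(enc$discharge[i] - enc$ed_arrival[i],
                                 units = "secs"))
      score <- if (subThreshold)
        sample(seq_len(threshold - 1L), length(i), replace = TRUE)
      else sample(threshold:10, length(i), replace = TRUE)
      data.frame(encounter_id = enc$encounter_id[i], timestamp = t,
                 model_score = as.integer(score),
                 chart_viewed = rep(subThreshold, length(i)))
    }
    # sub-threshold-but-viewed and fired-score-but-unviewed decoys
    out <- rbind(fired, decoy(TRUE), decoy(FALSE))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [plantSkeleton()], [synthesizeObservations()] and
#' [synthesizeAlerts()] under seeds derived from the configuration and
#' assembles a validated [SepsisCohort-class]. Identical configurations
#' produce identical cohorts.
#'
#' @param config a [scenarioConfig()].
#' @return list with `cohort` (SepsisCohort), `truth` (ground-truth
#'   data.frame) and `config`.
#' @export
#' @examples
#' sim <- simulateCohort(scenarioConfig(nEncounters = 100, seed = 7))
#' sim$cohort
simulateCohort <- function(config) {
  sk <- plantSkeleton(config)
  so <- synthesizeObservations(sk$truth, sk$encounterTable,
                               orderNoiseFraction = config$orderNoiseFraction,
                               seed = config$seed + 1L)
  al <- synthesizeAlerts(sk$truth, sk$encounterTable,
                         decoyAlertRate = config$decoyAlertRate,
                         seed = config$seed + 2L)
  cohort <- SepsisCohort(sk$encounterTable, so$observations,
                         so$orderEvents, al)
  validObject(cohort)
  list(cohort = cohort, truth = sk$truth, config = config)
}

#' Confusion matrix implied by the planted ground truth
#'
#' Classifies encounters directly from the ground-truth table, without
#' running the phenotype or alert extraction --- the oracle against which
#' the pipeline's round-trip recovery is checked.
#'
#' @param truth ground-truth data.frame from [plantSkeleton()].
#' @param windowHours forward horizon for windowed mode.
#' @param mode `"windowed"` or `"encounter"`.
#' @return a [ConfusionMatrix-class].
#' @export
truthConfusion <- function(truth, windowHours = 6,
                           mode = c("windowed", "encounter")) {
  mode <- match.arg(mode)
  tr <- as.data.frame(truth)
  alerted <- !is.na(tr$alert_time)
  if (mode == "encounter") {
    ConfusionMatrix(tp = sum(alerted & tr$sepsis),
                    fp = sum(alerted & !tr$sepsis),
                    fn = sum(!alerted & tr$sepsis),
                    tn = sum(!alerted & !tr$sepsis),
                    mode = "encounter", windowHours = Inf)
  } else {
    inWin <- alerted & tr$sepsis & !is.na(tr$onset_time) &
      tr$onset_time >= tr$alert_time &
      minutesBetween(tr$alert_time, tr$onset_time) <= windowHours * 60
    ConfusionMatrix(tp = sum(inWin), fp = sum(alerted & !inWin),
                    fn = sum(!alerted & tr$sepsis),
                    tn = sum(!alerted & !tr$sepsis),
                    mode = "windowed", windowHours = windowHours)
  }
}
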