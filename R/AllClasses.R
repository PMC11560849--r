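#' @import methods
#' @importFrom data.table data.table setDT setorder := .N .SD fread fwrite as.data.table setnames
#' @importFrom stats runif rbinom rlnorm median quantile chisq.test pchisq qnorm setNames
#' @importFrom utils head
NULL

## controlled vocabularies ----------------------------------------------------

.SEXES  <- c("female", "male")
.RACES  <- c("Asian", "Black", "Hispanic", "White", "Other")
.COMORBIDITIES <- c("diabetes", "hyperlipidemia", "chronic_kidney_disease",
                    "cabg", "pvd", "stroke")
.ORDER_KINDS <- c("blood_culture", "antibiotic")
.OBS_KINDS <- c("pf_ratio", "platelets", "bilirubin", "map", "gcs",
                "creatinine", "urine_output_24h", "dopamine", "dobutamine",
                "epinephrine", "norepinephrine", "ventilated")

#' Physiologic plausibility bounds per observation kind
#'
#' Observations outside these bounds are rejected at read time. The table is
#' an argument to [readCohort()] so site-specific limits can be substituted.
#' Units are fixed per kind: pf_ratio mmHg, platelets 10^3/uL, bilirubin and
#' creatinine mg/dL, MAP mmHg, GCS 3-15 (integer), 24-h urine output mL,
#' vasopressors ug/kg/min, ventilated 0/1.
#'
#' @return data.frame with columns `kind`, `min`, `max`.
#' @export
observationBounds <- function() {
  data.frame(
    kind = .OBS_KINDS,
    min  = c(1,    0,   0,   10, 3,  0,   0,     0, 0, 0, 0, 0),
    max  = c(1000, 2000, 60, 300, 15, 40, 20000, 100, 100, 10, 10, 1)
  )
}

## SepsisCohort ---------------------------------------------------------------

#' SepsisCohort: an EHR extract of ED-initiated encounters
#'
#' Container for the four cohort tables: encounters (demographics,
#' comorbidity flags, ED arrival / discharge bounds), timestamped
#' observations feeding the SOFA score, blood-culture / antibiotic order
#' events, and sepsis-model alert events. Validity enforces the invariants
#' every downstream stage assumes: adults only, discharge >= arrival,
#' in-bounds observation values, event timestamps inside their encounter
#' span, and referential integrity of `encounter_id` across tables.
#'
#' @slot encounters data.frame: `encounter_id`, `sex`, `age_years`, `race`,
#'   one logical column per comorbidity flag, `ed_arrival`, `discharge`
#'   (POSIXct, UTC).
#' @slot observations data.frame: `encounter_id`, `timestamp`, `kind`,
#'   `value`.
#' @slot orders data.frame: `encounter_id`, `timestamp`, `kind`.
#' @slot alerts data.frame: `encounter_id`, `timestamp`, `model_score`,
#'   `chart_viewed`.
#' @export
setClass("SepsisCohort", representation(
  encounters   = "data.frame",
  observations = "data.frame",
  orders       = "data.frame",
  alerts       = "data.frame"
))

.validSepsisCohort <- function(object) {
  enc <- object@encounters
  msgs <- character()
  need <- c("encounter_id", "sex", "age_years", "race", .COMORBIDITIES,
            "ed_arrival", "discharge")
  miss <- setdiff(need, names(enc))
  if (length(miss))
    return(paste("encounters missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(enc$encounter_id))
    msgs <- c(msgs, "duplicate encounter_id in encounters")
  if (nrow(enc)) {
    if (any(enc$age_years < 18, na.rm = TRUE))
      msgs <- c(msgs, "age_years < 18 (adult cohort only)")
    if (any(enc$discharge < enc$ed_arrival, na.rm = TRUE))
      msgs <- c(msgs, "discharge earlier than ed_arrival")
    if (!all(enc$sex %in% .SEXES)) msgs <- c(msgs, "invalid sex category")
    if (!all(enc$race %in% .RACES)) msgs <- c(msgs, "invalid race category")
  }
  arr <- setNames(enc$ed_arrival, enc$encounter_id)
  dis <- setNames(enc$discharge, enc$encounter_id)
  chkEvents <- function(tab, nm) {
    if (!nrow(tab)) return(character())
    m <- character()
    orphan <- !(tab$encounter_id %in% enc$encounter_id)
    if (any(orphan))
      m <- c(m, sprintf("%s references unknown encounter_id(s): %s", nm,
                        paste(unique(tab$encounter_id[orphan]), collapse = ", ")))
    inb <- tab$timestamp >= arr[tab$encounter_id] &
           tab$timestamp <= dis[tab$encounter_id]
    if (any(!inb, na.rm = TRUE) || anyNA(inb))
      m <- c(m, sprintf("%s timestamps outside encounter bounds", nm))
    m
  }
  msgs <- c(msgs, chkEvents(object@observations, "observations"),
            chkEvents(object@orders, "orders"),
            chkEvents(object@alerts, "alerts"))
  obs <- object@observations
  if (nrow(obs)) {
    if (!all(obs$kind %in% .OBS_KINDS))
      msgs <- c(msgs, "unknown observation kind")
    b <- observationBounds()
    lo <- setNames(b$min, b$kind)[obs$kind]
    hi <- setNames(b$max, b$kind)[obs$kind]
    if (any(obs$value < lo | obs$value > hi, na.rm = TRUE))
      msgs <- c(msgs, "observation value outside plausibility bounds")
    g <- obs$kind == "gcs"
    if (any(g) && any(obs$value[g] != round(obs$value[g])))
      msgs <- c(msgs, "gcs must be an integer in [3, 15]")
  }
  if (nrow(object@orders) && !all(object@orders$kind %in% .ORDER_KINDS))
    msgs <- c(msgs, "unknown order kind")
  if (length(msgs)) msgs else TRUE
}
setValidity("SepsisCohort", .validSepsisCohort)

#' Construct a SepsisCohort from its four tables
#'
#' @param encounters,observations,orders,alerts data.frames with the schemas
#'   documented in [SepsisCohort-class]. `observations`, `orders` and
#'   `alerts` may be omitted (empty tables).
#' @return validated [SepsisCohort-class] object.
#' @export
SepsisCohort <- function(encounters,
                         observations = emptyObservations(),
                         orders = emptyOrders(),
                         alerts = emptyAlerts()) {
  new("SepsisCohort",
      encounters = as.data.frame(encounters),
      observations = as.data.frame(observations),
      orders = as.data.frame(orders),
      alerts = as.data.frame(alerts))
}

.emptyTs <- function() as.POSIXct(character(), tz = "UTC")

#' @rdname SepsisCohort
#' @export
emptyObservations <- function()
  data.frame(encounter_id = character(), timestamp = .emptyTs(),
             kind = character(), value = numeric())

#' @rdname SepsisCohort
#' @export
emptyOrders <- function()
  data.frame(encounter_id = character(), timestamp = .emptyTs(),
             kind = character())

#' @rdname SepsisCohort
#' @export
emptyAlerts <- function()
  data.frame(encounter_id = character(), timestamp = .emptyTs(),
             model_score = integer(), chart_viewed = logical())

## SofaSeriesSet --------------------------------------------------------------

#' SofaSeriesSet: gridded SOFA scores for a cohort
#'
#' One row per encounter per grid time, holding the six organ sub-scores
#' (each 0-4), the total (0-24), and per-organ imputation flags marking grid
#' points where no observation fell inside the carry-forward lookback and
#' the sub-score defaulted to 0 (organ assumed normal).
#'
#' @slot scores data.frame: `encounter_id`, `grid_time`, `respiration`,
#'   `coagulation`, `liver`, `cardiovascular`, `cns`, `renal`, `total`, and
#'   logical `imputed_*` per organ.
#' @slot stepMinutes grid step (minutes).
#' @slot carryForwardHours LOCF lookback (hours).
#' @export
setClass("SofaSeriesSet", representation(
  scores = "data.frame",
  stepMinutes = "numeric",
  carryForwardHours = "numeric"
))

.SOFA_ORGANS <- c("respiration", "coagulation", "liver", "cardiovascular",
                  "cns", "renal")

setValidity("SofaSeriesSet", function(object) {
  sc <- object@scores
  need <- c("encounter_id", "grid_time", .SOFA_ORGANS, "total",
            paste0("imputed_", .SOFA_ORGANS))
  miss <- setdiff(need, names(sc))
  if (length(miss))
    return(paste("scores missing column(s):", paste(miss, collapse = ", ")))
  if (!nrow(sc)) return(TRUE)
  sub <- as.matrix(sc[, .SOFA_ORGANS])
  if (any(sub < 0 | sub > 4)) return("sub-scores must lie in 0..4")
  if (any(sc$total != rowSums(sub)))
    return("total must equal the sum of the six sub-scores")
  TRUE
})

## ConfusionMatrix ------------------------------------------------------------

#' ConfusionMatrix: alert-versus-sepsis classification counts
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @slot mode `"windowed"` (onset within a fixed horizon after the alert) or
#'   `"encounter"` (sepsis anywhere in the encounter).
#' @slot windowHours horizon used in windowed mode (`Inf` otherwise).
#' @export
setClass("ConfusionMatrix", representation(
  tp = "integer", fp = "integer", fn = "integer", tn = "integer",
  mode = "character", windowHours = "numeric"
))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(v) != 4L || anyNA(v)) return("tp/fp/fn/tn must be scalar counts")
  if (any(v < 0)) return("counts must be non-negative")
  if (!object@mode %in% c("windowed", "encounter"))
    return("mode must be 'windowed' or 'encounter'")
  TRUE
})

#' Construct a ConfusionMatrix from counts
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @param mode `"windowed"` or `"encounter"`.
#' @param windowHours horizon (hours) for windowed mode.
#' @return [ConfusionMatrix-class].
#' @export
ConfusionMatrix <- function(tp, fp, fn, tn, mode = "windowed",
                            windowHours = if (mode == "windowed") 6 else Inf) {
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn), mode = mode,
      windowHours = as.numeric(windowHours))
}
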