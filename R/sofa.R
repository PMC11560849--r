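#' SOFA organ sub-scores
#'
#' Vectorised scoring of the six Sequential Organ Failure Assessment organs
#' on the consensus 0-4 severity scale. Severity bins are left-closed at the
#' printed cutpoints: a value exactly at a threshold takes the milder score
#' (platelets exactly 100 scores 1; 99.9 scores 2). `NA` inputs propagate to
#' `NA` scores; the series builder ([computeSofaSeries()]) converts those to
#' the default 0 and flags them as imputed.
#'
#' * respiration: PaO2/FiO2 >= 400 scores 0, < 400 scores 1, < 300 scores 2,
#'   < 200 with respiratory support 3, < 100 with support 4; without support
#'   the score caps at 2.
#' * coagulation: platelets (10^3/uL) >= 150 / < 150 / < 100 / < 50 / < 20.
#' * liver: bilirubin (mg/dL) < 1.2 / < 2.0 / < 6.0 / < 12.0 / >= 12.0.
#' * cardiovascular: maximum over applicable rules -- MAP >= 70 and no
#'   support scores 0; MAP < 70 scores 1; dopamine <= 5 or any dobutamine 2;
#'   dopamine > 5 or epinephrine <= 0.1 or norepinephrine <= 0.1 scores 3;
#'   dopamine > 15 or epinephrine > 0.1 or norepinephrine > 0.1 scores 4
#'   (doses in ug/kg/min).
#' * cns: Glasgow Coma Scale 15 / 13-14 / 10-12 / 6-9 / < 6.
#' * renal: maximum of the creatinine pathway (mg/dL, < 1.2 / < 2.0 / < 3.5 /
#'   < 5.0 / >= 5.0) and the 24-h urine-output pathway (< 500 mL scores 3,
#'   < 200 mL scores 4).
#'
#' @param pf_ratio PaO2/FiO2 in mmHg (> 0).
#' @param ventilated logical; on mechanical ventilation / respiratory
#'   support. `NA` is treated as not ventilated.
#' @param platelets platelet count, 10^3/uL.
#' @param bilirubin total bilirubin, mg/dL.
#' @param gcs Glasgow Coma Scale, integer 3-15.
#' @param creatinine serum creatinine, mg/dL.
#' @param urine_output_24h 24-hour urine output, mL (optional pathway).
#' @param map mean arterial pressure, mmHg.
#' @param dopamine,dobutamine,epinephrine,norepinephrine infusion rates,
#'   ug/kg/min (0 or `NA` = not running).
#' @return integer vector of sub-scores in 0..4 (`NA` where the driving
#'   inputs are all `NA`).
#' @name sofaSubscores
NULL

#' @rdname sofaSubscores
#' @export
scoreRespiration <- function(pf_ratio, ventilated = FALSE) {
  if (any(pf_ratio <= 0, na.rm = TRUE))
    stop("pf_ratio must be positive", call. = FALSE)
  n <- max(length(pf_ratio), length(ventilated))
  pf <- rep_len(pf_ratio, n)
  vent <- rep_len(as.logical(ventilated), n)
  vent[is.na(vent)] <- FALSE
  s <- ifelse(pf >= 400, 0L, ifelse(pf >= 300, 1L, 2L))
  s[!is.na(pf) & pf < 200 & vent] <- 3L
  s[!is.na(pf) & pf < 100 & vent] <- 4L
  as.integer(s)
}

#' @rdname sofaSubscores
#' @export
scoreCoagulation <- function(platelets) {
  if (any(platelets < 0, na.rm = TRUE))
    stop("platelets must be non-negative", call. = FALSE)
  as.integer(ifelse(platelets >= 150, 0L,
              ifelse(platelets >= 100, 1L,
               ifelse(platelets >= 50, 2L,
                ifelse(platelets >= 20, 3L, 4L)))))
}

#' @rdname sofaSubscores
#' @export
scoreLiver <- function(bilirubin) {
  if (any(bilirubin < 0, na.rm = TRUE))
    stop("bilirubin must be non-negative", call. = FALSE)
  as.integer(ifelse(bilirubin < 1.2, 0L,
              ifelse(bilirubin < 2.0, 1L,
               ifelse(bilirubin < 6.0, 2L,
                ifelse(bilirubin < 12.0, 3L, 4L)))))
}

#' @rdname sofaSubscores
#' @export
scoreCns <- function(gcs) {
  if (any(gcs < 3 | gcs > 15, na.rm = TRUE))
    stop("gcs must lie in [3, 15]", call. = FALSE)
  as.integer(ifelse(gcs == 15, 0L,
              ifelse(gcs >= 13, 1L,
               ifelse(gcs >= 10, 2L,
                ifelse(gcs >= 6, 3L, 4L)))))
}

#' @rdname sofaSubscores
#' @export
scoreRenal <- function(creatinine, urine_output_24h = NA_real_) {
  if (any(creatinine < 0, na.rm = TRUE))
    stop("creatinine must be non-negative", call. = FALSE)
  if (any(urine_output_24h < 0, na.rm = TRUE))
    stop("urine_output_24h must be non-negative", call. = FALSE)
  n <- max(length(creatinine), length(urine_output_24h))
  cr <- rep_len(creatinine, n)
  uo <- rep_len(urine_output_24h, n)
  sc <- ifelse(cr < 1.2, 0L,
         ifelse(cr < 2.0, 1L,
          ifelse(cr < 3.5, 2L,
           ifelse(cr < 5.0, 3L, 4L))))
  su <- ifelse(uo < 200, 4L, ifelse(uo < 500, 3L, 0L))
  as.integer(pmax(sc, su, na.rm = TRUE) * ifelse(is.na(cr) & is.na(uo), NA, 1))
}

#' @rdname sofaSubscores
#' @export
scoreCardiovascular <- function(map, dopamine = 0, dobutamine = 0,
                                epinephrine = 0, norepinephrine = 0) {
  doses <- list(dopamine, dobutamine, epinephrine, norepinephrine)
  if (any(vapply(doses, function(d) any(d < 0, na.rm = TRUE), logical(1))))
    stop("vasopressor doses must be non-negative", call. = FALSE)
  n <- max(length(map), lengths(doses))
  map <- rep_len(map, n)
  dop <- rep_len(dopamine, n);      dop[is.na(dop)] <- 0
  dob <- rep_len(dobutamine, n);    dob[is.na(dob)] <- 0
  epi <- rep_len(epinephrine, n);   epi[is.na(epi)] <- 0
  nor <- rep_len(norepinephrine, n); nor[is.na(nor)] <- 0
  s <- integer(n)
  s[!is.na(map) & map < 70] <- 1L
  s <- pmax(s, ifelse((dop > 0 & dop <= 5) | dob > 0, 2L, 0L))
  s <- pmax(s, ifelse(dop > 5 | (epi > 0 & epi <= 0.1) |
                        (nor > 0 & nor <= 0.1), 3L, 0L))
  s <- pmax(s, ifelse(dop > 15 | epi > 0.1 | nor > 0.1, 4L, 0L))
  noSupport <- dop == 0 & dob == 0 & epi == 0 & nor == 0
  s[is.na(map) & noSupport] <- NA_integer_
  as.integer(s)
}

## gridded series -------------------------------------------------------------

# LOCF one observation kind onto the grid (roll window in seconds)
.locfKind <- function(grid, obs, k, rollSec) {
  o <- obs[obs$kind == k, c("encounter_id", "timestamp", "value")]
  if (!nrow(o)) return(rep(NA_real_, nrow(grid)))
  o <- data.table::as.data.table(o)
  # worst (most deranged) value per encounter x timestamp tie; latest row wins
  data.table::setorder(o, encounter_id, timestamp)
  data.table::setkeyv(o, c("encounter_id", "timestamp"))
  o[grid, on = c("encounter_id", "timestamp" = "grid_time"),
    roll = rollSec, x.value]
}

#' Compute gridded SOFA series for a cohort
#'
#' Evaluates the six organ sub-scores and the total SOFA at every grid time
#' (default every 15 minutes) from ED arrival through discharge of each
#' encounter. At each grid time each organ uses the most recent observation
#' within `carryForwardHours` (last observation carried forward); an organ
#' with no observation in the lookback defaults to 0 (assumed normal) and is
#' flagged in the `imputed_*` columns.
#'
#' @param cohort a [SepsisCohort-class].
#' @param stepMinutes grid step in minutes; must divide 60 (default 15).
#' @param carryForwardHours LOCF lookback in hours (default 24).
#' @return a [SofaSeriesSet-class].
#' @export
#' @examples
#' sim <- simulateCohort(scenarioConfig(nEncounters = 20, seed = 1))
#' sofa <- computeSofaSeries(sim$cohort)
#' head(sofaScores(sofa))
computeSofaSeries <- function(cohort, stepMinutes = 15,
                              carryForwardHours = 24) {
  stopifnot(is(cohort, "SepsisCohort"))
  if (60 %% stepMinutes != 0)
    stop("stepMinutes must divide 60", call. = FALSE)
  enc <- encounters(cohort)
  obs <- observations(cohort)
  if (!nrow(enc)) {
    return(new("SofaSeriesSet",
               scores = .emptySofaScores(),
               stepMinutes = stepMinutes,
               carryForwardHours = carryForwardHours))
  }
  nPts <- floor(minutesBetween(enc$ed_arrival, enc$discharge) / stepMinutes) + 1L
  grid <- data.table::data.table(
    encounter_id = rep(enc$encounter_id, nPts),
    grid_time = rep(enc$ed_arrival, nPts) +
      (sequence(nPts) - 1L) * stepMinutes * 60
  )
  data.table::setkeyv(grid, c("encounter_id", "grid_time"))
  rollSec <- carryForwardHours * 3600
  v <- lapply(setNames(.OBS_KINDS, .OBS_KINDS),
              function(k) .locfKind(grid, obs, k, rollSec))

  respiration <- scoreRespiration(v$pf_ratio, v$ventilated > 0)
  coagulation <- scoreCoagulation(v$platelets)
  liver       <- scoreLiver(v$bilirubin)
  cardiovascular <- scoreCardiovascular(v$map, v$dopamine, v$dobutamine,
                                        v$epinephrine, v$norepinephrine)
  cns   <- scoreCns(v$gcs)
  renal <- scoreRenal(v$creatinine, v$urine_output_24h)

  sub <- data.frame(respiration, coagulation, liver, cardiovascular,
                    cns, renal)
  imputed <- is.na(sub)
  sub[imputed] <- 0L
  colnames(imputed) <- paste0("imputed_", .SOFA_ORGANS)
  scores <- data.frame(
    encounter_id = grid$encounter_id,
    grid_time = grid$grid_time,
    sub,
    total = as.integer(rowSums(sub)),
    imputed
  )
  new("SofaSeriesSet", scores = scores, stepMinutes = stepMinutes,
      carryForwardHours = carryForwardHours)
}

.emptySofaScores <- function() {
  z <- data.frame(encounter_id = character(), grid_time = .emptyTs())
  for (o in .SOFA_ORGANS) z[[o]] <- integer()
  z$total <- integer()
  for (o in .SOFA_ORGANS) z[[paste0("imputed_", o)]] <- logical()
  z
}
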