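# shared builders and independent oracles for the test suite

ts <- function(x) parseTimestamp(x)

# one-encounter cohort builder; times are offsets in minutes from arrival
makeEncounterTable <- function(ids = "E1",
                               arrival = "2023-03-01T00:00:00Z",
                               losMinutes = 360) {
  n <- length(ids)
  arr <- rep(ts(arrival), length.out = n)
  enc <- data.frame(encounter_id = ids,
                    sex = rep("female", n), age_years = rep(50L, n),
                    race = rep("White", n))
  for (cm in c("diabetes", "hyperlipidemia", "chronic_kidney_disease",
               "cabg", "pvd", "stroke")) enc[[cm]] <- rep(FALSE, n)
  enc$ed_arrival <- arr
  enc$discharge <- arr + rep(losMinutes, length.out = n) * 60
  enc
}

obsAt <- function(id, minutes, kind, value, arrival = "2023-03-01T00:00:00Z") {
  data.frame(encounter_id = id, timestamp = ts(arrival) + minutes * 60,
             kind = kind, value = value)
}

orderAt <- function(id, minutes, kind, arrival = "2023-03-01T00:00:00Z") {
  data.frame(encounter_id = id, timestamp = ts(arrival) + minutes * 60,
             kind = kind)
}

alertAt <- function(id, minutes, score = 7, viewed = TRUE,
                    arrival = "2023-03-01T00:00:00Z") {
  data.frame(encounter_id = id, timestamp = ts(arrival) + minutes * 60,
             model_score = as.integer(score), chart_viewed = viewed)
}

# build a SofaSeriesSet directly from a vector of totals (one per 15-min
# grid step), distributing each total across organs in 0..4 chunks
makeSofaSet <- function(totals, id = "E1",
                        arrival = "2023-03-01T00:00:00Z") {
  organs <- c("respiration", "coagulation", "liver", "cardiovascular",
              "cns", "renal")
  sub <- t(vapply(as.integer(totals), function(tot) {
    x <- integer(6)
    for (k in seq_len(6)) { x[k] <- min(tot, 4L); tot <- tot - x[k] }
    x
  }, integer(6)))
  colnames(sub) <- organs
  sc <- data.frame(encounter_id = id,
                   grid_time = ts(arrival) + (seq_along(totals) - 1) * 900,
                   sub, total = as.integer(rowSums(sub)))
  for (o in organs) sc[[paste0("imputed_", o)]] <- FALSE
  new("SofaSeriesSet", scores = sc, stepMinutes = 15, carryForwardHours = 24)
}

bothOrders <- function(id = "E1", minutes = 30,
                       arrival = "2023-03-01T00:00:00Z") {
  rbind(orderAt(id, minutes, "blood_culture", arrival),
        orderAt(id, minutes, "antibiotic", arrival))
}

# labels table builder for evaluation tests; onset in minutes from a fixed
# origin, NA for no sepsis
makeLabels <- function(ids, sepsis, onsetMinutes = rep(NA_real_, length(ids)),
                       origin = "2023-03-01T00:00:00Z") {
  data.frame(encounter_id = ids, sepsis = sepsis,
             onset_time = ts(origin) + onsetMinutes * 60,
             baseline_sofa = 0L,
             onset_sofa = ifelse(sepsis, 2L, NA_integer_),
             orders_satisfied = sepsis)
}

firstAlertsAt <- function(ids, minutes, origin = "2023-03-01T00:00:00Z") {
  data.frame(encounter_id = ids, alert_time = ts(origin) + minutes * 60)
}

# --- independent SOFA oracle -------------------------------------------------
# cutpoint-counting lookups, deliberately structured differently from the
# implementation: severity = number of thresholds passed
oracleCoag <- function(p) vapply(p, function(v) sum(v < c(150, 100, 50, 20)), numeric(1))
oracleLiver <- function(b) vapply(b, function(v) sum(v >= c(1.2, 2.0, 6.0, 12.0)), numeric(1))
oracleCns <- function(g) vapply(g, function(v) sum(v < c(15, 13, 10, 6)), numeric(1))
oracleCreat <- function(cr) vapply(cr, function(v) sum(v >= c(1.2, 2.0, 3.5, 5.0)), numeric(1))
oracleRenal <- function(cr, uo) {
  u <- ifelse(is.na(uo), 0, ifelse(uo < 200, 4, ifelse(uo < 500, 3, 0)))
  pmax(oracleCreat(cr), u)
}
oracleResp <- function(pf, vent) {
  base <- vapply(pf, function(v) sum(v < c(400, 300, 200, 100)), numeric(1))
  ifelse(vent, base, pmin(base, 2))
}
oracleCardio <- function(map, dop = 0, dob = 0, epi = 0, nor = 0) {
  n <- max(length(map), length(dop), length(dob), length(epi), length(nor))
  map <- rep_len(map, n); dop <- rep_len(dop, n); dob <- rep_len(dob, n)
  epi <- rep_len(epi, n); nor <- rep_len(nor, n)
  vapply(seq_len(n), function(i) {
    if (dop[i] > 15 || epi[i] > 0.1 || nor[i] > 0.1) return(4)
    if (dop[i] > 5 || epi[i] > 0 || nor[i] > 0) return(3)
    if (dop[i] > 0 || dob[i] > 0) return(2)
    if (map[i] < 70) return(1)
    0
  }, numeric(1))
}

# reconstruct per-encounter label and first-alert tables from confusion-
# matrix category counts (the worked-example oracle for printed marginals)
reconstructFromCounts <- function(nTpWindow, nTpOutOfWindow, nAlertNoSepsis,
                                  nSepsisNoAlert, nNeither,
                                  origin = "2023-03-01T00:00:00Z") {
  total <- nTpWindow + nTpOutOfWindow + nAlertNoSepsis + nSepsisNoAlert +
    nNeither
  ids <- sprintf("R%06d", seq_len(total))
  grp <- rep(c("tpw", "tpo", "ans", "sna", "nn"),
             c(nTpWindow, nTpOutOfWindow, nAlertNoSepsis, nSepsisNoAlert,
               nNeither))
  sepsis <- grp %in% c("tpw", "tpo", "sna")
  onset <- rep(NA_real_, total)
  onset[grp == "tpw"] <- 120   # 1 h after its alert, inside 6-h window
  onset[grp == "tpo"] <- 60    # 1 h before its alert: outside the window
  onset[grp == "sna"] <- 120
  alertMin <- rep(NA_real_, total)
  alertMin[grp %in% c("tpw", "ans")] <- 60
  alertMin[grp == "tpo"] <- 120
  labels <- makeLabels(ids, sepsis, onset, origin)
  alerted <- !is.na(alertMin)
  fa <- firstAlertsAt(ids[alerted], alertMin[alerted], origin)
  list(labels = labels, firstAlerts = fa)
}
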