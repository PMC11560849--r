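test_that("organ sub-scores match an independent cutpoint-counting oracle", {
  set.seed(11)
  pf <- runif(300, 40, 600)
  vent <- runif(300) < 0.5
  expect_equal(scoreRespiration(pf, vent), as.integer(oracleResp(pf, vent)))
  plt <- runif(300, 1, 400)
  expect_equal(scoreCoagulation(plt), as.integer(oracleCoag(plt)))
  bil <- runif(300, 0, 25)
  expect_equal(scoreLiver(bil), as.integer(oracleLiver(bil)))
  gcs <- sample(3:15, 300, replace = TRUE)
  expect_equal(scoreCns(gcs), as.integer(oracleCns(gcs)))
  cr <- runif(300, 0.2, 9)
  uo <- sample(c(NA, 100, 300, 800, 2500), 300, replace = TRUE)
  expect_equal(scoreRenal(cr, uo), as.integer(oracleRenal(cr, uo)))
  map <- runif(300, 40, 110)
  dop <- sample(c(0, 0, 2, 8, 20), 300, replace = TRUE)
  dob <- sample(c(0, 0, 0, 3), 300, replace = TRUE)
  epi <- sample(c(0, 0, 0.05, 0.3), 300, replace = TRUE)
  nor <- sample(c(0, 0, 0.08, 0.2), 300, replace = TRUE)
  expect_equal(scoreCardiovascular(map, dop, dob, epi, nor),
               as.integer(oracleCardio(map, dop, dob, epi, nor)))
})

test_that("threshold boundaries are left-closed and support rules hold", {
  expect_identical(scoreRespiration(500, FALSE), 0L)
  expect_identical(scoreRespiration(150, TRUE), 3L)
  expect_identical(scoreRespiration(150, FALSE), 2L)  # no support caps at 2
  expect_identical(scoreCoagulation(c(160, 150, 100, 99.9, 20, 19.9)),
                   c(0L, 0L, 1L, 2L, 3L, 4L))
  expect_identical(scoreLiver(c(1.19, 1.2, 2.0, 5.99, 6.0, 12, 13)),
                   c(0L, 1L, 2L, 2L, 3L, 4L, 4L))
  expect_identical(scoreCns(c(15, 14, 13, 12, 10, 9, 6, 5, 3)),
                   c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_identical(scoreRenal(c(1.0, 1.2, 3.49, 5.0)), c(0L, 1L, 2L, 4L))
  expect_identical(scoreRenal(1.0, 150), 4L)  # urine pathway dominates
  expect_identical(scoreRenal(1.0, 450), 3L)
  expect_identical(scoreCardiovascular(80), 0L)
  expect_identical(scoreCardiovascular(65), 1L)
  expect_identical(scoreCardiovascular(60, norepinephrine = 0.2), 4L)
  expect_identical(scoreCardiovascular(90, dopamine = 4), 2L)
  expect_identical(scoreCardiovascular(90, dopamine = 6), 3L)
})

test_that("domain errors are raised for invalid inputs", {
  expect_error(scoreRespiration(0), "positive")
  expect_error(scoreCns(c(5, 16)), "\\[3, 15\\]")
  expect_error(scoreCns(2), "\\[3, 15\\]")
  expect_error(scoreCardiovascular(70, dopamine = -1), "non-negative")
})

test_that("worsening any single input never decreases its sub-score", {
  set.seed(23)
  for (i in 1:200) {
    plt <- runif(1, 5, 350)
    expect_gte(scoreCoagulation(plt), scoreCoagulation(plt + runif(1, 0, 50)))
    bil <- runif(1, 0, 20)
    expect_gte(scoreLiver(bil + runif(1, 0, 5)), scoreLiver(bil))
    cr <- runif(1, 0.3, 8)
    expect_gte(scoreRenal(cr + runif(1, 0, 3)), scoreRenal(cr))
    g <- sample(4:15, 1)
    expect_gte(scoreCns(g - 1), scoreCns(g))
    pf <- runif(1, 110, 550)
    v <- runif(1) < 0.5
    expect_gte(scoreRespiration(pf - runif(1, 0, 80), v),
               scoreRespiration(pf, v))
    map <- runif(1, 50, 100)
    nor <- sample(c(0, 0.05, 0.2), 1)
    expect_gte(scoreCardiovascular(map - runif(1, 0, 20), norepinephrine = nor),
               scoreCardiovascular(map, norepinephrine = nor))
    expect_gte(scoreCardiovascular(map, norepinephrine = nor + 0.1),
               scoreCardiovascular(map, norepinephrine = nor))
  }
})

test_that("gridded series: LOCF, defaults, imputation flags, alignment", {
  enc <- makeEncounterTable("E1", losMinutes = 26 * 60)
  # no observations at all: total 0 everywhere, everything imputed
  cohort <- SepsisCohort(enc)
  s <- sofaScores(computeSofaSeries(cohort))
  expect_equal(nrow(s), floor(26 * 60 / 15) + 1)
  expect_true(all(s$total == 0))
  expect_true(all(as.matrix(s[, grep("^imputed_", names(s))])))

  # single platelets=40 at t0: coagulation 3 until the 24-h lookback
  # expires, then back to default 0 (flagged)
  cohort <- SepsisCohort(enc, obsAt("E1", 0, "platelets", 40))
  s <- sofaScores(computeSofaSeries(cohort, carryForwardHours = 24))
  withinLookback <- minutesBetween(ts("2023-03-01T00:00:00Z"), s$grid_time) <=
    24 * 60
  expect_true(all(s$coagulation[withinLookback] == 3))
  expect_true(all(s$coagulation[!withinLookback] == 0))
  expect_false(any(s$imputed_coagulation[withinLookback]))
  expect_true(all(s$imputed_coagulation[!withinLookback]))

  # LOCF picks the most recent value before each grid time
  obs <- rbind(obsAt("E1", 0, "platelets", 200),
               obsAt("E1", 100, "platelets", 90))
  s <- sofaScores(computeSofaSeries(SepsisCohort(enc, obs)))
  expect_equal(s$coagulation[s$grid_time < ts("2023-03-01T01:40:00Z")],
               rep(0L, 7))
  fresh <- s$grid_time >= ts("2023-03-01T01:40:00Z") &
    minutesBetween(ts("2023-03-01T01:40:00Z"), s$grid_time) <= 24 * 60
  expect_true(all(s$coagulation[fresh] == 2))
})

test_that("series invariants: totals, ranges, idempotence, short stays", {
  sim <- simulateCohort(scenarioConfig(nEncounters = 120, seed = 5))
  s1 <- computeSofaSeries(sim$cohort)
  s2 <- computeSofaSeries(sim$cohort)
  expect_identical(sofaScores(s1), sofaScores(s2))
  sc <- sofaScores(s1)
  organs <- c("respiration", "coagulation", "liver", "cardiovascular",
              "cns", "renal")
  expect_true(all(as.matrix(sc[, organs]) >= 0))
  expect_true(all(as.matrix(sc[, organs]) <= 4))
  expect_true(all(sc$total >= 0 & sc$total <= 24))
  expect_identical(sc$total, as.integer(rowSums(sc[, organs])))
  # grid length per encounter
  enc <- encounters(sim$cohort)
  gl <- table(sc$encounter_id)[enc$encounter_id]
  expect_equal(as.integer(gl),
               floor(as.numeric(enc$discharge - enc$ed_arrival,
                                units = "mins") / 15) + 1L)
  # an encounter shorter than one step yields a single-point series
  short <- SepsisCohort(makeEncounterTable("S1", losMinutes = 10))
  expect_equal(nrow(sofaScores(computeSofaSeries(short))), 1L)
})
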