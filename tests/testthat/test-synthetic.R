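test_that("degenerate prevalences force the expected structure", {
  sk0 <- plantSkeleton(scenarioConfig(nEncounters = 100, seed = 1,
                                      sepsisPrevalence = 0))
  expect_equal(sum(sk0$truth$sepsis), 0)
  expect_true(all(is.na(sk0$truth$onset_time)))

  cfg1 <- scenarioConfig(
    nEncounters = 50, seed = 2, sepsisPrevalence = 1, alertPrevalence = 1,
    pAlertGivenSepsis = 1,
    leadTimeDistribution = list(family = "point_mass", params = list(at = 60)))
  sk1 <- plantSkeleton(cfg1)
  expect_true(all(sk1$truth$sepsis))
  expect_true(all(!is.na(sk1$truth$alert_time)))
  expect_equal(as.numeric(sk1$truth$onset_time - sk1$truth$alert_time,
                          units = "mins"), rep(60, 50))
})

test_that("realized prevalence stays within binomial sampling error", {
  n <- 20000
  p <- 0.037
  sk <- plantSkeleton(scenarioConfig(nEncounters = n, seed = 77))
  sdBin <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(sk$truth$sepsis) - p), 3 * sdBin)
  pa <- 0.049
  sdA <- sqrt(pa * (1 - pa) / n)
  expect_lt(abs(mean(!is.na(sk$truth$alert_time)) - pa), 3 * sdA)
})

test_that("infeasible joint alert/sepsis structure is a configuration error", {
  expect_error(scenarioConfig(nEncounters = 10, sepsisPrevalence = 0.5,
                              alertPrevalence = 0.1, pAlertGivenSepsis = 0.9),
               "infeasible")
})

test_that("planted times always lie inside their encounters", {
  sk <- plantSkeleton(scenarioConfig(nEncounters = 3000, seed = 11,
                                     sepsisPrevalence = 0.2,
                                     alertPrevalence = 0.2,
                                     pAlertGivenSepsis = 0.7))
  enc <- sk$encounterTable
  tr <- sk$truth
  iS <- !is.na(tr$onset_time)
  expect_true(all(tr$onset_time[iS] >= enc$ed_arrival[iS]))
  expect_true(all(tr$onset_time[iS] <= enc$discharge[iS]))
  iA <- !is.na(tr$alert_time)
  expect_true(all(tr$alert_time[iA] >= enc$ed_arrival[iA]))
  expect_true(all(tr$alert_time[iA] <= enc$discharge[iA]))
  # onset present iff sepsis; onsets sit on the 15-minute grid
  expect_identical(iS, tr$sepsis)
  offs <- as.numeric(tr$onset_time[iS] - enc$ed_arrival[iS], units = "mins")
  expect_true(all(offs %% 15 == 0))
})

test_that("decoy alerts are excluded from fired-alert extraction", {
  cfg <- scenarioConfig(nEncounters = 400, seed = 21, decoyAlertRate = 0.5)
  sim <- simulateCohort(cfg)
  ae <- alerts(sim$cohort)
  expect_true(any(ae$model_score < 6))
  expect_true(any(!ae$chart_viewed))
  fa <- extractFiredAlerts(ae)
  planted <- sim$truth[!is.na(sim$truth$alert_time), ]
  expect_setequal(fa$encounter_id, planted$encounter_id)
  expect_equal(fa$alert_time[match(planted$encounter_id, fa$encounter_id)],
               planted$alert_time)
})

test_that("identical config yields byte-identical cohort files", {
  cfg <- scenarioConfig(nEncounters = 60, seed = 12345)
  d1 <- tempfile("det1"); d2 <- tempfile("det2")
  writeCohort(simulateCohort(cfg)$cohort, d1)
  writeCohort(simulateCohort(cfg)$cohort, d2)
  for (f in c("encounters.csv", "observations.csv", "orders.csv",
              "alerts.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("plant -> synthesize -> label -> evaluate recovers the planted matrix", {
  cfg <- scenarioConfig(nEncounters = 2500, seed = 31)
  sim <- simulateCohort(cfg)
  labels <- labelCohort(computeSofaSeries(sim$cohort), orders(sim$cohort),
                        encounterIds = encounters(sim$cohort)$encounter_id)
  ev <- evaluateAlerts(labels, alerts(sim$cohort))
  expect_identical(counts(ev$windowed),
                   counts(truthConfusion(sim$truth, 6, "windowed")))
  expect_identical(counts(ev$encounter),
                   counts(truthConfusion(sim$truth, mode = "encounter")))
})

test_that("scenario configs round-trip through YAML", {
  cfg <- scenarioConfig(nEncounters = 40, seed = 4, sepsisPrevalence = 0.1,
                        alertPrevalence = 0.12, pAlertGivenSepsis = 0.6)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    nEncounters = 40, seed = 4, sepsisPrevalence = 0.1,
    alertPrevalence = 0.12, pAlertGivenSepsis = 0.6), f)
  cfg2 <- readScenarioConfig(f)
  expect_equal(cfg2$pAlertGivenNonSepsis, cfg$pAlertGivenNonSepsis)
  expect_identical(simulateCohort(cfg)$truth, simulateCohort(cfg2)$truth)
})
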