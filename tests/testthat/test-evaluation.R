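test_that("only viewed, at-threshold alerts fire; earliest per encounter", {
  # neither a sub-threshold viewed event nor an unviewed high score fires
  ae <- rbind(alertAt("E1", 10, score = 5, viewed = TRUE),
              alertAt("E1", 20, score = 7, viewed = FALSE))
  expect_equal(nrow(extractFiredAlerts(ae)), 0)
  # earliest qualifying event wins regardless of row order
  ae <- rbind(alertAt("E1", 60, score = 6, viewed = TRUE),
              alertAt("E1", 0, score = 9, viewed = TRUE))
  fa <- extractFiredAlerts(ae)
  expect_equal(fa$alert_time, ts("2023-03-01T00:00:00Z"))
  expect_equal(nrow(extractFiredAlerts(emptyAlerts())), 0)
  # threshold is configurable
  expect_equal(nrow(extractFiredAlerts(alertAt("E1", 5, score = 5), threshold = 5)), 1)
})

test_that("windowed classification follows the one-sided closed window", {
  labels <- makeLabels(c("A", "B", "C", "D", "E"),
                       sepsis = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                       onsetMinutes = c(240, 420, NA, 480, NA))
  # A: alert 0, onset 240 (4 h)  -> TP
  # B: alert 0, onset 420 (7 h)  -> FP (sepsis outside window)
  # C: alert 0, no sepsis        -> FP
  # D: no alert, sepsis          -> FN;  E: no alert, no sepsis -> TN
  fa <- firstAlertsAt(c("A", "B", "C"), c(0, 0, 0))
  cm <- windowedConfusion(fa, labels, windowHours = 6)
  expect_equal(counts(cm), c(tp = 1L, fp = 2L, fn = 1L, tn = 1L))
  # onset exactly at the 6-h horizon still counts (closed window)
  cm6 <- windowedConfusion(firstAlertsAt("A", 0),
                           makeLabels("A", TRUE, 360), windowHours = 6)
  expect_equal(counts(cm6)[["tp"]], 1L)
  # onset before the alert is outside the forward window
  cmNeg <- windowedConfusion(firstAlertsAt("A", 120),
                             makeLabels("A", TRUE, 60), windowHours = 6)
  expect_equal(counts(cmNeg)[["fp"]], 1L)
  # but is a TP at encounter level
  cmEnc <- encounterConfusion(firstAlertsAt("A", 120),
                              makeLabels("A", TRUE, 60))
  expect_equal(counts(cmEnc)[["tp"]], 1L)
  # id mismatch is a hard error
  expect_error(windowedConfusion(firstAlertsAt("ZZ", 0), labels), "ZZ")
})

test_that("windowed and encounter matrices share FN and TN", {
  sim <- simulateCohort(scenarioConfig(nEncounters = 600, seed = 17))
  labels <- labelCohort(computeSofaSeries(sim$cohort), orders(sim$cohort))
  ev <- evaluateAlerts(labels, alerts(sim$cohort))
  expect_equal(ev$windowed@fn, ev$encounter@fn)
  expect_equal(ev$windowed@tn, ev$encounter@tn)
  expect_equal(sum(counts(ev$windowed)), nrow(labels))
  expect_equal(sum(counts(ev$encounter)), nrow(labels))
})

test_that("widening the window never decreases TP and never increases FP", {
  sim <- simulateCohort(scenarioConfig(nEncounters = 800, seed = 19))
  labels <- labelCohort(computeSofaSeries(sim$cohort), orders(sim$cohort))
  fa <- extractFiredAlerts(alerts(sim$cohort))
  cms <- lapply(c(1, 3, 6, 12, 48, Inf), function(w)
    windowedConfusion(fa, labels, windowHours = w))
  tp <- vapply(cms, function(cm) cm@tp, integer(1))
  fp <- vapply(cms, function(cm) cm@fp, integer(1))
  expect_true(all(diff(tp) >= 0))
  expect_true(all(diff(fp) <= 0))
})

test_that("diagnostic metrics equal their defining ratios, with Wilson CIs", {
  m <- diagnosticMetrics(ConfusionMatrix(10, 30, 5, 955))
  est <- setNames(m$estimate, m$metric)
  expect_equal(est[["sensitivity"]], 10 / 15)
  expect_equal(est[["specificity"]], 955 / 985)
  expect_equal(est[["ppv"]], 10 / 40)
  expect_equal(est[["npv"]], 955 / 960)
  expect_true(all(m$lower <= m$estimate & m$estimate <= m$upper))
  # Wilson interval cross-checked against prop.test (without correction)
  pt <- prop.test(10, 15, correct = FALSE)
  expect_equal(unname(unlist(m[m$metric == "sensitivity", c("lower", "upper")])),
               as.numeric(pt$conf.int), tolerance = 1e-10)
  # perfect classifier
  perfect <- diagnosticMetrics(ConfusionMatrix(1, 0, 0, 1))
  expect_equal(perfect$estimate, rep(1, 4))
  # zero denominators are undefined, not 0
  deg <- diagnosticMetrics(ConfusionMatrix(0, 0, 0, 10))
  est <- setNames(deg$estimate, deg$metric)
  expect_true(is.na(est[["sensitivity"]]))
  expect_true(is.na(est[["ppv"]]))
  expect_equal(est[["specificity"]], 1)
})
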