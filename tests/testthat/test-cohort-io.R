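writeReadDir <- function() file.path(tempfile("cohort"), "")

test_that("write then read reproduces the cohort exactly", {
  sim <- simulateCohort(scenarioConfig(nEncounters = 80, seed = 3))
  d <- tempfile("rt")
  writeCohort(sim$cohort, d)
  back <- readCohort(d)
  expect_equal(nrow(attr(back, "rejected")), 0)
  expect_equal(encounters(back), encounters(sim$cohort))
  expect_equal(observations(back), observations(sim$cohort))
  expect_equal(orders(back), orders(sim$cohort))
  expect_equal(alerts(back), alerts(sim$cohort))
})

test_that("empty tables round-trip as headers only", {
  enc <- makeEncounterTable("E1")
  cohort <- SepsisCohort(enc)
  d <- tempfile("empty")
  paths <- writeCohort(cohort, d)
  expect_equal(length(readLines(paths[["observations"]])), 1L) # header only
  back <- readCohort(d)
  expect_equal(nrow(observations(back)), 0)
  expect_equal(nrow(encounters(back)), 1)
})

test_that("non-ASCII encounter ids survive a UTF-8 round trip", {
  id <- "éñ-测试-001"
  cohort <- SepsisCohort(makeEncounterTable(id),
                         obsAt(id, 30, "platelets", 120))
  d <- tempfile("utf8")
  writeCohort(cohort, d)
  back <- readCohort(d)
  expect_identical(encounters(back)$encounter_id, id)
  expect_identical(observations(back)$encounter_id, id)
})

test_that("schema and referential problems are hard errors", {
  sim <- simulateCohort(scenarioConfig(nEncounters = 5, seed = 9))
  d <- tempfile("schema")
  paths <- writeCohort(sim$cohort, d)
  # drop a required column
  x <- read.csv(paths[["observations"]])
  write.csv(x[, setdiff(names(x), "kind")], paths[["observations"]],
            row.names = FALSE)
  expect_error(readCohort(d), "kind")
  # orphan encounter_id in orders
  writeCohort(sim$cohort, d)
  cat("GHOST,2023-05-01T00:00:00Z,antibiotic\n",
      file = paths[["orders"]], append = TRUE)
  expect_error(readCohort(d), "GHOST")
  expect_error(readCohort(tempfile("nope")), "not found|does not exist")
})

test_that("invariant-violating rows are rejected with line diagnostics", {
  enc <- makeEncounterTable("E1", losMinutes = 120)
  cohort <- SepsisCohort(enc, obsAt("E1", 30, "platelets", 120))
  d <- tempfile("rows")
  paths <- writeCohort(cohort, d)
  # gcs out of range, and a timestamp outside the encounter bounds
  cat("E1,2023-03-01T00:30:00Z,gcs,17\n", file = paths[["observations"]],
      append = TRUE)
  cat("E1,2023-04-01T00:00:00Z,platelets,200\n",
      file = paths[["observations"]], append = TRUE)
  cat("E1,not-a-time,platelets,200\n", file = paths[["observations"]],
      append = TRUE)
  back <- readCohort(d)
  rej <- attr(back, "rejected")
  expect_equal(nrow(rej), 3)
  expect_true(any(grepl("gcs", rej$reason)))
  expect_true(any(grepl("outside encounter bounds", rej$reason)))
  expect_true(any(grepl("timestamp", rej$reason)))
  expect_equal(sort(rej$line), c(3L, 4L, 5L))
  # accepted + rejected account for every input row
  nIn <- length(readLines(paths[["observations"]])) - 1L
  expect_equal(nrow(observations(back)) + sum(rej$table == "observations"),
               nIn)
})

test_that("round trip preserves arbitrary valid cohorts (property)", {
  for (s in c(101, 202, 303)) {
    sim <- simulateCohort(scenarioConfig(nEncounters = 30, seed = s,
                                         sepsisPrevalence = 0.2,
                                         alertPrevalence = 0.25,
                                         pAlertGivenSepsis = 0.5))
    d <- tempfile(paste0("prop", s))
    writeCohort(sim$cohort, d)
    back <- readCohort(d)
    expect_equal(encounters(back), encounters(sim$cohort))
    expect_equal(observations(back), observations(sim$cohort))
    expect_equal(orders(back), orders(sim$cohort))
    expect_equal(alerts(back), alerts(sim$cohort))
  }
})

test_that("cohort validity catches bad objects at construction", {
  enc <- makeEncounterTable("E1")
  encKid <- enc; encKid$age_years <- 12L
  expect_error(SepsisCohort(encKid), "age")
  encRev <- enc; encRev$discharge <- encRev$ed_arrival - 60
  expect_error(SepsisCohort(encRev), "discharge")
  expect_error(SepsisCohort(enc, obsAt("E1", 30, "gcs", 17)), "bounds")
  expect_error(SepsisCohort(enc, obsAt("EX", 30, "gcs", 12)), "unknown")
})
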