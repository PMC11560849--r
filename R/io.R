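#' Read and write cohort tables
#'
#' A cohort on disk is four comma-separated UTF-8 files with header rows:
#'
#' * `encounters.csv`: `encounter_id,sex,age_years,race,diabetes,
#'   hyperlipidemia,chronic_kidney_disease,cabg,pvd,stroke,ed_arrival,
#'   discharge`
#' * `observations.csv`: `encounter_id,timestamp,kind,value`
#' * `orders.csv`: `encounter_id,timestamp,kind`
#' * `alerts.csv`: `encounter_id,timestamp,model_score,chart_viewed`
#'
#' Timestamps are ISO-8601 with explicit offset (written as UTC `...Z`).
#' `readCohort()` validates row by row: a missing column raises a schema
#' error naming the column; an event row whose `encounter_id` is unknown
#' raises a referential error; rows with unparseable timestamps,
#' out-of-bounds values or other invariant violations are rejected and
#' reported in the `rejected` attribute of the result (one diagnostic per
#' row, with file and line number). Accepted plus rejected rows always
#' account for every input row.
#'
#' @param paths named list/vector with elements `encounters`,
#'   `observations`, `orders`, `alerts`, or a single directory containing
#'   the four standard file names.
#' @param bounds plausibility-bounds table, see [observationBounds()].
#' @return `readCohort()`: a [SepsisCohort-class] with attribute
#'   `rejected`, a data.frame (`table`, `line`, `encounter_id`, `reason`)
#'   of rejected rows. `writeCohort()`: the four paths, invisibly.
#' @export
readCohort <- function(paths, bounds = observationBounds()) {
  paths <- .cohortPaths(paths, mustExist = TRUE)
  rej <- list()
  note <- function(tab, line, id, reason) {
    rej[[length(rej) + 1L]] <<- data.frame(
      table = tab, line = line, encounter_id = id, reason = reason)
  }

  enc <- .readTable(paths[["encounters"]], "encounters",
                    c("encounter_id", "sex", "age_years", "race",
                      .COMORBIDITIES, "ed_arrival", "discharge"))
  enc$age_years <- suppressWarnings(as.integer(enc$age_years))
  for (cm in .COMORBIDITIES) enc[[cm]] <- .asLogical(enc[[cm]])
  enc$ed_arrival <- parseTimestamp(enc$ed_arrival)
  enc$discharge <- parseTimestamp(enc$discharge)
  bad <- rep("", nrow(enc))
  bad[is.na(enc$ed_arrival) | is.na(enc$discharge)] <- "unparseable timestamp"
  bad[bad == "" & enc$discharge < enc$ed_arrival] <- "discharge before ed_arrival"
  bad[bad == "" & (is.na(enc$age_years) | enc$age_years < 18)] <-
    "age_years must be an integer >= 18"
  bad[bad == "" & !(enc$sex %in% .SEXES)] <- "invalid sex category"
  bad[bad == "" & !(enc$race %in% .RACES)] <- "invalid race category"
  bad[bad == "" & duplicated(enc$encounter_id)] <- "duplicate encounter_id"
  for (i in which(bad != ""))
    note("encounters", i + 1L, enc$encounter_id[i], bad[i])
  enc <- enc[bad == "", , drop = FALSE]

  arr <- setNames(enc$ed_arrival, enc$encounter_id)
  dis <- setNames(enc$discharge, enc$encounter_id)
  readEvents <- function(path, tab, cols) {
    x <- .readTable(path, tab, cols)
    ts <- parseTimestamp(x$timestamp)
    orphan <- !(x$encounter_id %in% enc$encounter_id)
    if (any(orphan))
      stop(sprintf("%s: unknown encounter_id(s): %s", tab,
                   paste(unique(x$encounter_id[orphan]), collapse = ", ")),
           call. = FALSE)
    bad <- rep("", nrow(x))
    bad[is.na(ts)] <- "unparseable timestamp"
    inb <- ts >= arr[x$encounter_id] & ts <= dis[x$encounter_id]
    bad[bad == "" & !inb] <- "timestamp outside encounter bounds"
    x$timestamp <- ts
    list(x = x, bad = bad)
  }

  ob <- readEvents(paths[["observations"]], "observations",
                   c("encounter_id", "timestamp", "kind", "value"))
  obs <- ob$x
  obs$value <- suppressWarnings(as.numeric(obs$value))
  bad <- ob$bad
  bad[bad == "" & !(obs$kind %in% .OBS_KINDS)] <- "unknown observation kind"
  lo <- setNames(bounds$min, bounds$kind)[obs$kind]
  hi <- setNames(bounds$max, bounds$kind)[obs$kind]
  oob <- bad == "" & (is.na(obs$value) | obs$value < lo | obs$value > hi |
                        (obs$kind == "gcs" & obs$value != round(obs$value)))
  bad[oob] <- sprintf("value violates bounds for kind '%s'", obs$kind[oob])
  for (i in which(bad != ""))
    note("observations", i + 1L, obs$encounter_id[i], bad[i])
  obs <- obs[bad == "", , drop = FALSE]

  or <- readEvents(paths[["orders"]], "orders",
                   c("encounter_id", "timestamp", "kind"))
  ords <- or$x
  bad <- or$bad
  bad[bad == "" & !(ords$kind %in% .ORDER_KINDS)] <- "unknown order kind"
  for (i in which(bad != ""))
    note("orders", i + 1L, ords$encounter_id[i], bad[i])
  ords <- ords[bad == "", , drop = FALSE]

  al <- readEvents(paths[["alerts"]], "alerts",
                   c("encounter_id", "timestamp", "model_score",
                     "chart_viewed"))
  alr <- al$x
  alr$model_score <- suppressWarnings(as.integer(alr$model_score))
  alr$chart_viewed <- .asLogical(alr$chart_viewed)
  bad <- al$bad
  bad[bad == "" & is.na(alr$model_score)] <- "unparseable model_score"
  bad[bad == "" & is.na(alr$chart_viewed)] <- "unparseable chart_viewed"
  for (i in which(bad != ""))
    note("alerts", i + 1L, alr$encounter_id[i], bad[i])
  alr <- alr[bad == "", , drop = FALSE]

  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(table = character(), line = integer(),
               encounter_id = character(), reason = character())
  rownames(enc) <- rownames(obs) <- rownames(ords) <- rownames(alr) <- NULL
  cohort <- SepsisCohort(enc, obs, ords, alr)
  attr(cohort, "rejected") <- rejected
  cohort
}

#' @rdname readCohort
#' @param cohort a [SepsisCohort-class].
#' @export
writeCohort <- function(cohort, paths) {
  stopifnot(is(cohort, "SepsisCohort"))
  validObject(cohort)
  paths <- .cohortPaths(paths, mustExist = FALSE)
  fmtTab <- function(x) {
    for (nm in names(x))
      if (inherits(x[[nm]], "POSIXct")) x[[nm]] <- formatTimestamp(x[[nm]])
    x
  }
  data.table::fwrite(fmtTab(encounters(cohort)), paths[["encounters"]])
  data.table::fwrite(fmtTab(observations(cohort)), paths[["observations"]])
  data.table::fwrite(fmtTab(orders(cohort)), paths[["orders"]])
  data.table::fwrite(fmtTab(alerts(cohort)), paths[["alerts"]])
  invisible(paths)
}

.cohortPaths <- function(paths, mustExist) {
  tabs <- c("encounters", "observations", "orders", "alerts")
  if (length(paths) == 1L && is.null(names(paths))) {
    d <- paths[[1]]
    if (mustExist && !dir.exists(d))
      stop("directory does not exist: ", d, call. = FALSE)
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    paths <- setNames(file.path(d, paste0(tabs, ".csv")), tabs)
  }
  paths <- unlist(paths)
  miss <- setdiff(tabs, names(paths))
  if (length(miss))
    stop("paths must name files for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (mustExist) {
    absent <- paths[tabs][!file.exists(paths[tabs])]
    if (length(absent))
      stop("file(s) not found: ", paste(absent, collapse = ", "),
           call. = FALSE)
  }
  paths[tabs]
}

.readTable <- function(path, tab, cols) {
  x <- as.data.frame(data.table::fread(path, colClasses = "character",
                                       encoding = "UTF-8", sep = ","))
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", tab,
                 paste(miss, collapse = ", ")), call. = FALSE)
  x[, cols, drop = FALSE]
}

.asLogical <- function(x) {
  y <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[y %in% c("TRUE", "T", "1")] <- TRUE
  out[y %in% c("FALSE", "F", "0")] <- FALSE
  out
}
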