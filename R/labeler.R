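#' Sepsis-3 electronic phenotype: onset detection and cohort labelling
#'
#' Sepsis is labelled when (i) the total SOFA score rises by 2 or more
#' points over the encounter baseline and (ii) at least one blood culture
#' AND at least one antibiotic were ordered at any time during the
#' encounter. Onset is the earliest grid time at which the two-point rise
#' first holds. The baseline is either the first computed grid score
#' (`baselineMode = "first_score"`, default) or 0 (`"zero"`, the consensus
#' assumption of no pre-existing organ dysfunction); under `"zero"` an
#' encounter whose very first grid score is already >= 2 has onset at the
#' first grid time.
#'
#' @param sofa a [SofaSeriesSet-class].
#' @param orderEvents data.frame of order events (`encounter_id`,
#'   `timestamp`, `kind` in `blood_culture`/`antibiotic`), e.g.
#'   `orders(cohort)`.
#' @param baselineMode `"first_score"` or `"zero"`.
#' @param encounterIds optional character vector of encounter ids that must
#'   each have a SOFA series; ids missing from `sofa` raise an error listing
#'   them. Defaults to the encounters present in `sofa`.
#' @param quiet suppress the one-line prevalence summary message.
#' @return data.frame with one row per encounter: `encounter_id`, `sepsis`
#'   (logical), `onset_time` (POSIXct, `NA` unless sepsis), `baseline_sofa`,
#'   `onset_sofa` (`NA` unless sepsis), `orders_satisfied`.
#' @export
#' @examples
#' sim <- simulateCohort(scenarioConfig(nEncounters = 50, seed = 2))
#' labels <- labelCohort(computeSofaSeries(sim$cohort), orders(sim$cohort))
#' table(labels$sepsis)
labelCohort <- function(sofa, orderEvents,
                        baselineMode = c("first_score", "zero"),
                        encounterIds = NULL, quiet = TRUE) {
  stopifnot(is(sofa, "SofaSeriesSet"))
  baselineMode <- match.arg(baselineMode)
  sc <- data.table::as.data.table(sofa@scores)
  dup <- sc[, .N, by = c("encounter_id", "grid_time")][N > 1L]
  if (nrow(dup))
    stop("duplicate SOFA series rows for encounter(s): ",
         paste(unique(dup$encounter_id), collapse = ", "), call. = FALSE)
  ids <- unique(sc$encounter_id)
  if (!is.null(encounterIds)) {
    missing <- setdiff(encounterIds, ids)
    if (length(missing))
      stop("no SOFA series for encounter(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    ids <- encounterIds
  }
  data.table::setorder(sc, encounter_id, grid_time)
  lab <- sc[, {
    base <- if (baselineMode == "first_score") total[1L] else 0L
    hit <- which(total >= base + 2L)
    list(baseline_sofa = as.integer(base),
         crossing_time = if (length(hit)) grid_time[hit[1L]] else
           as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"),
         crossing_sofa = if (length(hit)) total[hit[1L]] else NA_integer_)
  }, by = "encounter_id"]

  oe <- as.data.frame(orderEvents)
  hasBc <- unique(oe$encounter_id[oe$kind == "blood_culture"])
  hasAb <- unique(oe$encounter_id[oe$kind == "antibiotic"])
  lab[, `:=`(orders_satisfied = encounter_id %in% hasBc &
               encounter_id %in% hasAb)]
  lab[, sepsis := orders_satisfied & !is.na(crossing_time)]
  lab[, onset_time := data.table::fifelse(sepsis, crossing_time,
        as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"))]
  lab[, onset_sofa := ifelse(sepsis, crossing_sofa, NA_integer_)]
  out <- as.data.frame(lab[match(ids, lab$encounter_id),
                           c("encounter_id", "sepsis", "onset_time",
                             "baseline_sofa", "onset_sofa",
                             "orders_satisfied")])
  rownames(out) <- NULL
  attr(out, "baseline_mode") <- baselineMode
  if (!quiet)
    message(sprintf("labelled %d encounters: %d sepsis (%.1f%%)",
                    nrow(out), sum(out$sepsis),
                    100 * mean(out$sepsis)))
  out
}

#' @rdname labelCohort
#' @details `detectOnset()` is the single-encounter form: it requires `sofa`
#'   to contain exactly one encounter and returns its one-row label.
#' @export
detectOnset <- function(sofa, orderEvents,
                        baselineMode = c("first_score", "zero")) {
  stopifnot(is(sofa, "SofaSeriesSet"))
  ids <- unique(sofa@scores$encounter_id)
  if (length(ids) != 1L)
    stop("detectOnset() expects a single-encounter SofaSeriesSet; got ",
         length(ids), call. = FALSE)
  labelCohort(sofa, orderEvents, baselineMode = baselineMode)
}
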