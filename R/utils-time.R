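#' Parse ISO-8601 timestamps to UTC
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with an explicit numeric offset
#' (`+HH:MM`, `+HHMM`) or `Z`, or a bare `YYYY-MM-DD HH:MM:SS` string which is
#' taken as UTC. All values are normalised to UTC `POSIXct` so that interval
#' arithmetic (grids, windows, lead times) is timezone-safe.
#'
#' @param x character vector of timestamps.
#' @return `POSIXct` vector in UTC; unparseable entries are `NA`.
#' @export
#' @examples
#' parseTimestamp("2023-03-01T08:15:00Z")
#' parseTimestamp("2023-03-01T03:15:00-05:00")
parseTimestamp <- function(x) {
  x <- as.character(x)
  out <- rep(as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"), length(x))
  if (!length(x)) return(out)
  y <- sub("Z$", "+0000", x)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  has_off <- grepl("[+-][0-9]{4}$", y)
  if (any(has_off)) {
    p <- as.POSIXct(strptime(y[has_off], "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"))
    out[has_off] <- p
  }
  if (any(!has_off)) {
    bare <- gsub("T", " ", y[!has_off], fixed = TRUE)
    p <- as.POSIXct(strptime(bare, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    out[!has_off] <- p
  }
  out
}

#' Format UTC timestamps as ISO-8601
#'
#' @param t `POSIXct` vector.
#' @return character vector `YYYY-MM-DDTHH:MM:SSZ` (UTC, second precision).
#' @export
formatTimestamp <- function(t) {
  ifelse(is.na(t), NA_character_,
         format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

# signed difference b - a in minutes
minutesBetween <- function(a, b) as.numeric(difftime(b, a, units = "mins"))

#' Evaluation grid times for one encounter
#'
#' The grid starts at ED arrival and advances in `stepMinutes` steps while
#' grid time <= discharge; an encounter shorter than one step yields a
#' single-point grid.
#'
#' @param edArrival,discharge `POSIXct` bounds of the encounter.
#' @param stepMinutes grid step in minutes (default 15).
#' @return `POSIXct` vector of grid times.
#' @export
gridTimes <- function(edArrival, discharge, stepMinutes = 15) {
  stopifnot(length(edArrival) == 1L, length(discharge) == 1L,
            discharge >= edArrival)
  n <- floor(minutesBetween(edArrival, discharge) / stepMinutes) + 1L
  edArrival + (seq_len(n) - 1L) * stepMinutes * 60
}

# run code under a private RNG stream, restoring the caller's state
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
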