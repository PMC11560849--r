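#' Accessors for cohort and result containers
#'
#' `encounters()`, `observations()`, `orders()` and `alerts()` return the
#' component tables of a [SepsisCohort-class]; `sofaScores()` returns the
#' long score table of a [SofaSeriesSet-class]; `counts()` returns the four
#' cells of a [ConfusionMatrix-class] as a named integer vector.
#'
#' @param x the container object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("encounters", function(x) standardGeneric("encounters"))
#' @rdname accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))
#' @rdname accessors
#' @export
setGeneric("orders", function(x) standardGeneric("orders"))
#' @rdname accessors
#' @export
setGeneric("alerts", function(x) standardGeneric("alerts"))
#' @rdname accessors
#' @export
setGeneric("sofaScores", function(x) standardGeneric("sofaScores"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setMethod("encounters", "SepsisCohort", function(x) x@encounters)
#' @rdname accessors
#' @export
setMethod("observations", "SepsisCohort", function(x) x@observations)
#' @rdname accessors
#' @export
setMethod("orders", "SepsisCohort", function(x) x@orders)
#' @rdname accessors
#' @export
setMethod("alerts", "SepsisCohort", function(x) x@alerts)
#' @rdname accessors
#' @export
setMethod("sofaScores", "SofaSeriesSet", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("counts", "ConfusionMatrix", function(x)
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))

setMethod("show", "SepsisCohort", function(object) {
  enc <- object@encounters
  cat("SepsisCohort with", nrow(enc), "encounters\n")
  cat("  observations:", nrow(object@observations),
      " orders:", nrow(object@orders),
      " alerts:", nrow(object@alerts), "\n")
  if (nrow(enc))
    cat("  span:", formatTimestamp(min(enc$ed_arrival)), "to",
        formatTimestamp(max(enc$discharge)), "\n")
})

setMethod("show", "SofaSeriesSet", function(object) {
  sc <- object@scores
  cat("SofaSeriesSet:", length(unique(sc$encounter_id)), "encounters,",
      nrow(sc), "grid points (", object@stepMinutes, "min step,",
      object@carryForwardHours, "h carry-forward )\n")
  if (nrow(sc))
    cat("  total SOFA range:", min(sc$total), "-", max(sc$total), "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (%s%s)\n", object@mode,
              if (is.finite(object@windowHours))
                sprintf(", %g h window", object@windowHours) else ""))
  m <- matrix(c(object@tp, object@fp, object@fn, object@tn), 2, byrow = TRUE,
              dimnames = list(c("alert+", "alert-"),
                              c("sepsis", "no sepsis")))
  print(m)
})
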