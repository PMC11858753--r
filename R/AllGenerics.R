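#' @include AllClasses.R
NULL

#' @title Accessors for cfikit objects
#' @name accessors
#' @description Slot accessors; user code should use these rather than
#'   \code{@} access.
#' @param object a cfikit S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))

#' @rdname accessors
#' @export
setGeneric("epochSeconds", function(object) standardGeneric("epochSeconds"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("binValues", function(object) standardGeneric("binValues"))

#' @rdname accessors
#' @export
setGeneric("binsPerDay", function(object) standardGeneric("binsPerDay"))

#' @rdname accessors
#' @export
setGeneric("nDays", function(object) standardGeneric("nDays"))

#' @rdname accessors
#' @export
setGeneric("cfi", function(object) standardGeneric("cfi"))

#' @rdname accessors
#' @export
setGeneric("posteriorSummary", function(object) standardGeneric("posteriorSummary"))

#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname accessors
#' @export
setGeneric("randomIntercepts", function(object) standardGeneric("randomIntercepts"))

setMethod("subjectId", "ActigraphyRecording", function(object) object@subjectId)
setMethod("activity", "ActigraphyRecording", function(object) object@activity)
setMethod("epochSeconds", "ActigraphyRecording", function(object) object@epochSeconds)
setMethod("startTime", "ActigraphyRecording", function(object) object@startTime)
setMethod("missingMask", "ActigraphyRecording", function(object) object@missingMask)

setMethod("binValues", "BinnedSeries", function(object) object@values)
setMethod("binsPerDay", "BinnedSeries", function(object) object@binsPerDay)
setMethod("nDays", "BinnedSeries", function(object) object@nDays)

setMethod("subjectId", "NPCRAResult", function(object) object@subjectId)
setMethod("cfi", "NPCRAResult", function(object) object@CFI)
setMethod("nDays", "NPCRAResult", function(object) object@nDays)

setMethod("posteriorSummary", "HierFit", function(object) object@summary)
setMethod("posteriorDraws", "HierFit", function(object) object@draws)
setMethod("randomIntercepts", "HierFit", function(object) object@ranef)

setMethod("show", "ActigraphyRecording", function(object) {
  n <- length(object@activity)
  cat("ActigraphyRecording '", object@subjectId, "'\n", sep = "")
  cat(sprintf("  %d epochs of %d s (%.2f days) from %s\n", n,
              object@epochSeconds, n * object@epochSeconds / 86400,
              format(object@startTime, "%Y-%m-%d %H:%M:%S %Z")))
  cat(sprintf("  missing: %d epochs (%.1f%%)\n", sum(object@missingMask),
              100 * mean(object@missingMask)))
})

setMethod("show", "BinnedSeries", function(object) {
  cat(sprintf("BinnedSeries: %d bins/day x %d days (%d bins", object@binsPerDay,
              object@nDays, length(object@values)))
  if (anyNA(object@values)) cat(sprintf(", %d NA", sum(is.na(object@values))))
  cat(")\n")
})

setMethod("show", "NPCRAResult", function(object) {
  cat("NPCRAResult '", object@subjectId, "' (", object@nDays, " days)\n",
      sep = "")
  cat(sprintf("  IS = %.3f  IV = %.3f (inv-norm %.3f)  RA = %.3f\n",
              object@IS, object@IV, object@IVinvNorm, object@RA))
  cat(sprintf("  M10 = %.1f @ %02.0f:00  L5 = %.1f @ %02.0f:00\n",
              object@M10, object@M10onsetHour, object@L5, object@L5onsetHour))
  cat(sprintf("  CFI = %.3f\n", object@CFI))
})

setMethod("show", "HierFit", function(object) {
  cat("Bayesian hierarchical fit: outcome '", object@model, "'\n", sep = "")
  cat("  terms:", paste(object@terms, collapse = " + "),
      if (nrow(object@ranef)) "+ (1 | group)" else "", "\n")
  cat(sprintf("  %d observations, %d draws, max split-Rhat %.3f\n",
              nrow(object@data), coda::niter(object@draws) * length(object@draws),
              max(object@diagnostics$rhat)))
  print(object@summary, digits = 3, row.names = FALSE)
})

setMethod("show", "MoranResult", function(object) {
  cat(sprintf("Moran's I: %.4f (null expectation %.4f), p = %.4g\n",
              object@I, object@expectedI, object@pValue))
  cat(sprintf("  %d units, weights: %s, %d permutations\n", object@nUnits,
              object@weightScheme, object@nPermutations))
})

#' Flatten NPCRA results to a data.frame
#'
#' @param x an \code{NPCRAResult} or a list of them.
#' @param ... ignored.
#' @return data.frame with one row per subject and one column per statistic.
#' @export
as.data.frame.NPCRAResult <- function(x, ...) {
  data.frame(
    subject_id = x@subjectId, IS = x@IS, IV = x@IV, RA = x@RA,
    M10 = x@M10, L5 = x@L5, M10_onset_hour = x@M10onsetHour,
    L5_onset_hour = x@L5onsetHour, IV_inv_norm = x@IVinvNorm,
    CFI = x@CFI, n_days = x@nDays, stringsAsFactors = FALSE
  )
}

setMethod("as.data.frame", "NPCRAResult",
          function(x, ...) as.data.frame.NPCRAResult(x, ...))

#' @rdname as.data.frame.NPCRAResult
#' @param results list of \code{NPCRAResult} objects.
#' @export
npcraTable <- function(results) {
  if (is(results, "NPCRAResult")) results <- list(results)
  do.call(rbind, lapply(results, as.data.frame.NPCRAResult))
}
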