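#' @include AllClasses.R
NULL

#' Accessors for PepCoverage classes
#'
#' @param x A PepCoverage object.
#' @return \code{records}, \code{matches}, \code{unmatchedRecords} and
#'   \code{quantTable} return \code{DataFrame}s; \code{conditionFields},
#'   \code{targetIds}, \code{metric} and \code{groupBy} return character
#'   vectors; \code{targetSequences} returns an \code{AAStringSet};
#'   \code{targetRegions} and \code{targetMeta} return \code{DataFrame}s.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("conditionFields", function(x) standardGeneric("conditionFields"))
#' @rdname accessors
#' @export
setGeneric("targetSequences", function(x) standardGeneric("targetSequences"))
#' @rdname accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))
#' @rdname accessors
#' @export
setGeneric("targetRegions", function(x) standardGeneric("targetRegions"))
#' @rdname accessors
#' @export
setGeneric("targetMeta", function(x) standardGeneric("targetMeta"))
#' @rdname accessors
#' @export
setGeneric("matches", function(x) standardGeneric("matches"))
#' @rdname accessors
#' @export
setGeneric("unmatchedRecords", function(x) standardGeneric("unmatchedRecords"))
#' @rdname accessors
#' @export
setGeneric("quantTable", function(x) standardGeneric("quantTable"))
#' @rdname accessors
#' @export
setGeneric("metric", function(x) standardGeneric("metric"))
#' @rdname accessors
#' @export
setGeneric("groupBy", function(x) standardGeneric("groupBy"))

#' @rdname accessors
setMethod("records", "PeptideSet", function(x) x@records)
#' @rdname accessors
setMethod("conditionFields", "PeptideSet", function(x) x@conditionFields)
#' @rdname accessors
setMethod("targetSequences", "TargetSet", function(x) x@sequences)
#' @rdname accessors
setMethod("targetIds", "TargetSet", function(x) names(x@sequences))
#' @rdname accessors
setMethod("targetRegions", "TargetSet", function(x) x@regions)
#' @rdname accessors
setMethod("targetMeta", "TargetSet", function(x) x@targetMeta)
#' @rdname accessors
setMethod("matches", "MatchSet", function(x) x@matches)
#' @rdname accessors
setMethod("unmatchedRecords", "MatchSet", function(x) x@unmatched)
#' @rdname accessors
setMethod("quantTable", "PositionQuant", function(x) x@quant)
#' @rdname accessors
setMethod("metric", "PositionQuant", function(x) x@metric)
#' @rdname accessors
setMethod("groupBy", "PositionQuant", function(x) x@groupBy)

#' @rdname accessors
setMethod("length", "PeptideSet", function(x) nrow(x@records))
#' @rdname accessors
setMethod("length", "TargetSet", function(x) length(x@sequences))
#' @rdname accessors
setMethod("length", "MatchSet", function(x) nrow(x@matches))

setMethod("show", "PeptideSet", function(object) {
  cat(sprintf("PeptideSet with %d record(s) from %d file(s)\n",
              nrow(object@records),
              length(unique(object@records$source_file))))
  if (length(object@conditionFields))
    cat("  condition fields:",
        paste(object@conditionFields, collapse = ", "), "\n")
  qp <- vapply(c("psm", "intensity", "area"),
               function(f) sum(!is.na(object@records[[f]])), 0L)
  cat(sprintf("  quant present: psm=%d intensity=%d area=%d\n",
              qp[1], qp[2], qp[3]))
})

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet with %d target(s), %d region annotation(s)\n",
              length(object@sequences), nrow(object@regions)))
  w <- width(object@sequences)
  cat(sprintf("  lengths: %s\n",
              paste(sprintf("%s=%d", names(object@sequences), w),
                    collapse = ", ")))
})

setMethod("show", "MatchSet", function(object) {
  cat(sprintf("MatchSet with %d match(es); %d unmatched record(s)\n",
              nrow(object@matches), nrow(object@unmatched)))
})

setMethod("show", "PositionQuant", function(object) {
  cat(sprintf("PositionQuant (%s) over %d position row(s)",
              object@metric, nrow(object@quant)))
  if (length(object@groupBy))
    cat(sprintf("; grouped by %s", paste(object@groupBy, collapse = " x ")))
  cat("\n")
})
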