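#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Residue alphabet shared across the package: the 20 standard amino acids,
## the degenerate codes B (Asn/Asp), Z (Glu/Gln), X (any), and the rare
## residues U (Sec) and O (Pyl).
RESIDUE_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                      "B", "Z", "X", "U", "O")

#' PeptideSet: canonical table of peptide identifications
#'
#' One row per identified peptide occurrence, normalized from any supported
#' search-engine dialect. Quantitative fields (\code{psm}, \code{intensity},
#' \code{area}, \code{charge}) are \code{NA} when the source file did not
#' provide them; absence is deliberately distinct from zero.
#'
#' @slot records A \code{DataFrame} with at least \code{record_id},
#'   \code{source_file}, \code{modified_sequence}, \code{stripped_sequence},
#'   \code{psm}, \code{intensity}, \code{area}, \code{charge}, plus one
#'   column per condition field.
#' @slot conditionFields Character vector naming the condition columns
#'   (e.g. \code{donor}, \code{antibody}).
#' @exportClass PeptideSet
setClass("PeptideSet",
         slots = c(records = "DataFrame", conditionFields = "character"))

setValidity("PeptideSet", function(object) {
  rec <- object@records
  need <- c("record_id", "source_file", "modified_sequence",
            "stripped_sequence", "psm", "intensity", "area", "charge")
  miss <- setdiff(need, colnames(rec))
  if (length(miss))
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(rec$record_id))
    return("record_id values must be unique")
  if (nrow(rec)) {
    empty_both <- (is.na(rec$modified_sequence) | rec$modified_sequence == "") &
      (is.na(rec$stripped_sequence) | rec$stripped_sequence == "")
    if (any(empty_both))
      return("every record needs a modified or a stripped sequence")
    for (qc in c("psm", "intensity", "area")) {
      v <- rec[[qc]]
      if (any(!is.na(v) & v < 0))
        return(sprintf("negative values in '%s'", qc))
    }
  }
  if (!all(object@conditionFields %in% colnames(rec)))
    return("conditionFields must name columns of records")
  TRUE
})

#' TargetSet: protein/chain sequences with region annotations
#'
#' Target sequences may contain the degenerate codes B, Z, X. Regions are
#' 1-based inclusive intervals labelled as domain, CDR, mutation or other.
#'
#' @slot sequences \code{AAStringSet}, names are target ids.
#' @slot targetMeta \code{DataFrame} keyed by \code{target_id} with an
#'   optional \code{chain} column and arbitrary metadata for joining
#'   against peptide condition fields.
#' @slot regions \code{DataFrame} with \code{target_id}, \code{label},
#'   \code{start}, \code{end}, \code{category}.
#' @exportClass TargetSet
setClass("TargetSet",
         slots = c(sequences = "AAStringSet",
                   targetMeta = "DataFrame",
                   regions = "DataFrame"))

setValidity("TargetSet", function(object) {
  if (!length(object@sequences)) return("at least one target sequence required")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    return("sequences must have unique names (target ids)")
  chars <- unique(unlist(strsplit(as.character(object@sequences), "")))
  bad <- setdiff(chars, RESIDUE_ALPHABET)
  if (length(bad))
    return(paste("sequence characters outside residue alphabet:",
                 paste(bad, collapse = ", ")))
  if (any(width(object@sequences) == 0)) return("empty target sequence")
  reg <- object@regions
  if (nrow(reg)) {
    need <- c("target_id", "label", "start", "end", "category")
    miss <- setdiff(need, colnames(reg))
    if (length(miss))
      return(paste("missing region columns:", paste(miss, collapse = ", ")))
    if (!all(reg$target_id %in% names(object@sequences)))
      return("region references unknown target_id")
    len <- setNames(width(object@sequences), names(object@sequences))
    if (any(reg$start < 1 | reg$start > reg$end |
              reg$end > len[reg$target_id]))
      return("region interval outside 1..target length or start > end")
    if (any(is.na(reg$label) | reg$label == ""))
      return("region labels must be non-empty")
    if (!all(reg$category %in% c("domain", "cdr", "mutation", "other")))
      return("region category must be domain/cdr/mutation/other")
  }
  TRUE
})

#' MatchSet: peptide occurrences placed on targets
#'
#' @slot matches \code{DataFrame} with \code{record_id}, \code{target_id},
#'   \code{start}, \code{end} (1-based inclusive) and, after
#'   \code{annotateRegions}, a \code{region_labels} \code{CharacterList}.
#' @slot unmatched \code{DataFrame} of records that matched no target.
#' @exportClass MatchSet
setClass("MatchSet",
         slots = c(matches = "DataFrame", unmatched = "DataFrame"))

setValidity("MatchSet", function(object) {
  m <- object@matches
  need <- c("record_id", "target_id", "start", "end")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    return(paste("missing match columns:", paste(miss, collapse = ", ")))
  if (nrow(m) && any(m$start < 1 | m$end < m$start))
    return("match coordinates must satisfy 1 <= start <= end")
  TRUE
})

#' PositionQuant: per-residue metric values per grouping key
#'
#' @slot quant \code{DataFrame} with \code{target_id}, the grouping
#'   columns, \code{position}, \code{value}.
#' @slot metric One of \code{"psm"}, \code{"intensity"}, \code{"area"}.
#' @slot groupBy Character vector of grouping column names (may be empty).
#' @exportClass PositionQuant
setClass("PositionQuant",
         slots = c(quant = "DataFrame", metric = "character",
                   groupBy = "character"))

setValidity("PositionQuant", function(object) {
  if (!object@metric %in% c("psm", "intensity", "area"))
    return("metric must be psm, intensity or area")
  q <- object@quant
  need <- c("target_id", "position", "value", object@groupBy)
  miss <- setdiff(need, colnames(q))
  if (length(miss))
    return(paste("missing quant columns:", paste(miss, collapse = ", ")))
  if (nrow(q)) {
    if (any(q$value < 0)) return("negative quant value")
    key <- do.call(paste, c(as.list(as.data.frame(
      q[, c("target_id", object@groupBy, "position"), drop = FALSE])),
      sep = "\r"))
    if (anyDuplicated(key))
      return("duplicate (target, group, position) rows")
  }
  TRUE
})
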