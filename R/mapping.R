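## Degeneracy-aware peptide-to-target matching. Mass spectrometry cannot
## distinguish Ile from Leu, and database sequences may carry the
## degenerate codes B (Asn/Asp), Z (Glu/Gln) and X (any residue). Each
## residue therefore matches a *class* of residues, and a peptide matches
## a target window when every position's classes are compatible.

## Residue equivalence classes. The table is symmetric by construction:
## a is in class(b) iff b is in class(a). Class member order defines the
## canonical pattern rendering (ambiguity partners before X; I/L share
## the single rendering [ILX]).
residueClassTable <- function() {
  base <- setNames(lapply(RESIDUE_ALPHABET, function(r) c(r, "X")),
                   RESIDUE_ALPHABET)
  base$N <- c("N", "B", "X")
  base$D <- c("D", "B", "X")
  base$E <- c("E", "Z", "X")
  base$Q <- c("Q", "Z", "X")
  ## I and L share one class and one rendering, [ILX]
  base$I <- c("I", "L", "X")
  base$L <- c("I", "L", "X")
  base$B <- c("B", "N", "D", "X")
  base$Z <- c("Z", "E", "Q", "X")
  base$X <- c("X", setdiff(RESIDUE_ALPHABET, "X"))
  base
}

## 25x25 logical compatibility matrix, rows/cols indexed by residue letter.
residueCompatMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- residueClassTable()
      M <- matrix(FALSE, length(RESIDUE_ALPHABET), length(RESIDUE_ALPHABET),
                  dimnames = list(RESIDUE_ALPHABET, RESIDUE_ALPHABET))
      for (r in RESIDUE_ALPHABET) M[r, tab[[r]]] <- TRUE
      cache <<- M
    }
    cache
  }
})

#' Expand a stripped peptide into its degeneracy match pattern
#'
#' Each residue becomes the ordered class of residues it matches:
#' N and D pair with B, E and Q pair with Z, I and L are interchangeable,
#' X matches everything, and every unambiguous residue pairs only with X.
#' The canonical string rendering of \code{"NDEQIL"} is
#' \code{"[NBX][DBX][EZX][QZX][ILX][ILX]"}.
#'
#' @param peptide Stripped peptide string (may be empty).
#' @return Character string rendering of the pattern, one
#'   bracketed class per residue; \code{attr(,"classes")} holds the list
#'   of class vectors.
#' @examples
#' expandDegenerate("NDEQIL")
#' @export
expandDegenerate <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  chars <- strsplit(peptide, "")[[1]]
  tab <- residueClassTable()
  bad <- which(!chars %in% RESIDUE_ALPHABET)
  if (length(bad))
    stop(sprintf("character '%s' at offset %d outside residue alphabet",
                 chars[bad[1]], bad[1]))
  classes <- tab[chars]
  out <- paste(vapply(classes,
                      function(cl) paste0("[", paste(cl, collapse = ""), "]"),
                      character(1)),
               collapse = "")
  attr(out, "classes") <- unname(classes)
  out
}

## All 1-based start offsets where the peptide's classes match the target.
## Vectorized over offsets: one compatibility-matrix lookup per peptide
## position.
matchOffsets <- function(pep_idx, tgt_idx, M) {
  n <- length(pep_idx); L <- length(tgt_idx)
  if (n == 0L || L < n) return(integer(0))
  starts <- seq_len(L - n + 1L)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(n)) {
    ok <- ok & M[cbind(pep_idx[j], tgt_idx[starts + j - 1L])]
    if (!any(ok)) return(integer(0))
  }
  starts[ok]
}

residueIndex <- function(s) {
  idx <- match(strsplit(s, "")[[1]], RESIDUE_ALPHABET)
  if (anyNA(idx))
    stop("sequence contains characters outside the residue alphabet: ", s)
  idx
}

#' Map stripped peptides onto target sequences
#'
#' Every record/target pair passing the join is scanned at every offset;
#' all (possibly overlapping) degeneracy-class matches are reported. A
#' peptide occurring at several sites yields several rows. Records that
#' match no target are collected in the unmatched summary.
#'
#' @param ps A \code{PeptideSet} with stripped sequences populated.
#' @param targets A \code{TargetSet}.
#' @param join_on Optional character vector of field names present both as
#'   peptide condition fields and as target metadata columns; only
#'   record/target pairs agreeing on all of them are scanned. Default
#'   \code{NULL} matches every record against every target (cartesian).
#' @return A \code{MatchSet}; matches carry \code{record_id},
#'   \code{target_id}, \code{start}, \code{end} (1-based inclusive).
#' @examples
#' tgt <- targetSet(c(T1 = "AANDEQILGG"))
#' ps <- peptideSet(data.frame(stripped_sequence = "NDEQIL"))
#' matches(matchPeptides(ps, tgt))
#' @export
matchPeptides <- function(ps, targets, join_on = NULL) {
  stopifnot(is(ps, "PeptideSet"), is(targets, "TargetSet"))
  if (!length(targets@sequences)) stop("empty target list")
  rec <- ps@records
  if (any(is.na(rec$stripped_sequence) | rec$stripped_sequence == ""))
    stop("stripped_sequence must be populated on all records; ",
         "run processSequences() first")
  if (!is.null(join_on)) {
    miss_p <- setdiff(join_on, colnames(rec))
    miss_t <- setdiff(join_on, colnames(targets@targetMeta))
    if (length(miss_p) || length(miss_t))
      stop("join_on key(s) missing: ",
           paste(unique(c(miss_p, miss_t)), collapse = ", "))
  }
  M <- residueCompatMatrix()
  tgt_chr <- as.character(targets@sequences)
  tgt_idx <- lapply(tgt_chr, residueIndex)
  tmeta <- targets@targetMeta
  ## scan each distinct peptide sequence once per target
  uniq <- unique(rec$stripped_sequence)
  offs <- vector("list", length(uniq))
  names(offs) <- uniq
  for (u in uniq) {
    pidx <- residueIndex(u)
    offs[[u]] <- lapply(tgt_idx, function(ti) matchOffsets(pidx, ti, M))
  }
  out <- list()
  matched <- logical(nrow(rec))
  tids <- names(targets@sequences)
  for (i in seq_len(nrow(rec))) {
    seq_i <- rec$stripped_sequence[i]
    plen <- nchar(seq_i)
    for (t in seq_along(tids)) {
      if (!is.null(join_on)) {
        agree <- vapply(join_on, function(k) {
          tv <- tmeta[[k]][match(tids[t], tmeta$target_id)]
          identical(as.character(rec[[k]][i]), as.character(tv))
        }, logical(1))
        if (!all(agree)) next
      }
      st <- offs[[seq_i]][[t]]
      if (length(st)) {
        matched[i] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          record_id = rec$record_id[i], target_id = tids[t],
          start = st, end = st + plen - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  mtab <- if (length(out)) DataFrame(do.call(rbind, out))
          else DataFrame(record_id = character(0), target_id = character(0),
                         start = integer(0), end = integer(0))
  un <- rec[!matched, intersect(c("record_id", "stripped_sequence",
                                  ps@conditionFields), colnames(rec)),
            drop = FALSE]
  new("MatchSet", matches = mtab, unmatched = un)
}

#' Attach overlapping region labels to matches
#'
#' A region label is attached to a match iff their 1-based inclusive
#' intervals share at least one residue; labels are ordered by region
#' start.
#'
#' @param ms A \code{MatchSet}.
#' @param targets A \code{TargetSet} whose regions are used.
#' @return The \code{MatchSet} with a \code{region_labels}
#'   \code{CharacterList} column on the matches.
#' @importFrom IRanges IRanges findOverlaps CharacterList
#' @importFrom S4Vectors queryHits subjectHits
#' @export
annotateRegions <- function(ms, targets) {
  stopifnot(is(ms, "MatchSet"), is(targets, "TargetSet"))
  m <- ms@matches
  reg <- targets@regions
  if (nrow(reg) && !all(reg$target_id %in% names(targets@sequences)))
    stop("region references unknown target_id: ",
         paste(setdiff(reg$target_id, names(targets@sequences)),
               collapse = ", "))
  labels <- vector("list", nrow(m))
  for (i in seq_along(labels)) labels[[i]] <- character(0)
  if (nrow(m) && nrow(reg)) {
    for (tid in unique(m$target_id)) {
      mi <- which(m$target_id == tid)
      ri <- which(reg$target_id == tid)
      if (!length(ri)) next
      ri <- ri[order(reg$start[ri])]
      hits <- findOverlaps(IRanges(m$start[mi], m$end[mi]),
                           IRanges(reg$start[ri], reg$end[ri]))
      for (h in seq_along(queryHits(hits))) {
        q <- mi[queryHits(hits)[h]]
        labels[[q]] <- c(labels[[q]], reg$label[ri[subjectHits(hits)[h]]])
      }
    }
  }
  m$region_labels <- CharacterList(labels)
  initialize(ms, matches = m)
}
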