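## Sequence processing: strip modification notation from peptide strings
## and expand modifications into per-PTM positional records.

DEFAULT_PTM_PALETTE <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3",
                         "#FF7F00", "#A65628", "#F781BF", "#999999")

## Core scanner shared by stripSequence and extractPtms. Walks the peptide
## string once, removing flanking residues and terminal markers per the
## grammar, counting residue letters, and collecting each delimited
## annotation payload together with the number of residues seen before it
## (which is its 1-based position on the stripped peptide).
scanModifiedSequence <- function(x, grammar) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- x
  if (isTRUE(grammar$flanking)) {
    s <- sub("^[A-Z-]\\.", "", s)
    s <- sub("\\.[A-Z-]$", "", s)
  }
  term <- grammar$terminal
  has_terminal <- !is.na(term) || isTRUE(grammar$nc_markers)
  if (!is.na(term)) {
    s <- sub(paste0("^\\", term), "", s)
    s <- sub(paste0("\\", term, "$"), "", s)
  }
  chars <- strsplit(s, "")[[1]]
  open <- grammar$open; close <- grammar$close
  residues <- character(0)
  anns <- list()
  pending_terminal <- NA_character_
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == open) {
      depth <- 1L; j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > n)
          stop(sprintf("unbalanced '%s' at offset %d in '%s'", open, i, x))
        if (chars[j] == open) depth <- depth + 1L
        if (chars[j] == close) depth <- depth - 1L
      }
      payload <- paste(chars[seq(i + 1L, length.out = j - i - 1L)],
                       collapse = "")
      pos <- length(residues)
      terminal <- pending_terminal
      if (is.na(terminal) && pos == 0L) {
        if (!has_terminal)
          stop(sprintf(paste0("annotation before any residue at offset %d",
                              " in '%s' but grammar has no terminal",
                              " convention"), i, x))
        terminal <- "NTERM"
      }
      anns[[length(anns) + 1L]] <-
        list(payload = payload, position = pos, terminal = terminal)
      pending_terminal <- NA_character_
      i <- j + 1L
    } else if (ch == close) {
      stop(sprintf("unbalanced '%s' at offset %d in '%s'", close, i, x))
    } else if (isTRUE(grammar$nc_markers) && ch %in% c("n", "c") &&
                 i < n && chars[i + 1L] == open) {
      pending_terminal <- if (ch == "n") "NTERM" else "CTERM"
      i <- i + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      up <- toupper(ch)
      if (!up %in% RESIDUE_ALPHABET)
        stop(sprintf("residual non-residue character '%s' at offset %d in '%s'",
                     ch, i, x))
      residues <- c(residues, up)
      i <- i + 1L
    } else {
      stop(sprintf("residual non-residue character '%s' at offset %d in '%s'",
                   ch, i, x))
    }
  }
  list(stripped = paste(residues, collapse = ""), annotations = anns)
}

#' Strip modification notation from a peptide string
#'
#' Removes flanking residues (\code{"K.PEPTIDE.R"}), terminal markers
#' (enclosing underscores), lowercase n/c terminal prefixes, and all
#' delimited modification annotations (including nested delimiters such
#' as \code{"(Phospho (S))"}), returning the plain uppercase residue
#' string in original order.
#'
#' @param x Character vector of modified peptide strings.
#' @param grammar A modification grammar list (see \code{\link{dialectSpec}})
#'   or a platform name whose built-in grammar should be used.
#' @return Character vector of stripped sequences.
#' @examples
#' stripSequence("K.PEPS[79.9663]TIDE.R", "comet")
#' stripSequence("_AC(Phospho (S))DEFK_", "maxquant")
#' @export
stripSequence <- function(x, grammar = "maxquant") {
  if (is.character(grammar))
    grammar <- resolveDialect(grammar)$grammar
  vapply(x, function(s) scanModifiedSequence(s, grammar)$stripped,
         character(1), USE.NAMES = FALSE)
}

## Canonical rendering of a modification payload as a display label.
ptmLabel <- function(payload, kind) {
  if (kind == "mass") {
    m <- suppressWarnings(as.numeric(payload))
    if (is.na(m)) return(payload)
    sprintf("%+.2f", m)
  } else if (kind == "unimod") {
    sub("^[Uu]ni[Mm]od:", "UniMod:", payload)
  } else payload
}

ptmMass <- function(payload, kind) {
  if (kind == "mass") suppressWarnings(as.numeric(payload)) else NA_real_
}

#' Read a PTM annotation table
#'
#' Tabular control of PTM display: columns \code{ptm_key} (a modification
#' name, a UniMod accession, or a mass delta), \code{display_label} and
#' \code{display_color} (hex string or R color name). Numeric keys are
#' matched against mass-delta modifications within \code{tolerance}.
#'
#' @param path TSV/CSV file path.
#' @param tolerance Mass-matching tolerance in Da (default 0.01).
#' @return A \code{data.frame} with class attribute
#'   \code{"PTMAnnotationTable"}.
#' @export
readPtmTable <- function(path, tolerance = 0.01) {
  tab <- as.data.frame(data.table::fread(path, sep = "auto",
                                         colClasses = "character"))
  need <- c("ptm_key", "display_label", "display_color")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("PTM table missing column(s): ", paste(miss, collapse = ", "))
  ptmAnnotationTable(tab$ptm_key, tab$display_label, tab$display_color,
                     tolerance)
}

#' @rdname readPtmTable
#' @param ptm_key,display_label,display_color Vectors building the table
#'   in code.
#' @export
ptmAnnotationTable <- function(ptm_key, display_label, display_color,
                               tolerance = 0.01) {
  if (anyDuplicated(ptm_key))
    stop("duplicate ptm_key in PTM annotation table")
  if (tolerance < 0) stop("tolerance must be >= 0")
  structure(data.frame(ptm_key = as.character(ptm_key),
                       display_label = as.character(display_label),
                       display_color = as.character(display_color),
                       stringsAsFactors = FALSE),
            tolerance = tolerance, class = c("PTMAnnotationTable",
                                             "data.frame"))
}

## Join PTM labels/masses against a user annotation table; unmatched keys
## keep their raw label and draw a color from a fixed cycling palette.
joinPtmTable <- function(labels, masses, ptm_table) {
  n <- length(labels)
  out_label <- labels
  out_color <- rep(NA_character_, n)
  if (!is.null(ptm_table) && nrow(ptm_table)) {
    tol <- attr(ptm_table, "tolerance") %||% 0.01
    key_num <- suppressWarnings(as.numeric(ptm_table$ptm_key))
    for (i in seq_len(n)) {
      hit <- which(ptm_table$ptm_key == labels[i])
      if (!length(hit) && !is.na(masses[i]))
        hit <- which(!is.na(key_num) & abs(key_num - masses[i]) <= tol)
      if (length(hit)) {
        hit <- hit[1L]
        out_label[i] <- ptm_table$display_label[hit]
        out_color[i] <- ptm_table$display_color[hit]
      }
    }
  }
  unknown <- is.na(out_color)
  if (any(unknown)) {
    lv <- sort(unique(out_label[unknown]))
    pal <- rep_len(DEFAULT_PTM_PALETTE, length(lv))
    out_color[unknown] <- pal[match(out_label[unknown], lv)]
  }
  list(label = out_label, color = out_color)
}

#' Fill stripped sequences on a PeptideSet
#'
#' Applies \code{\link{stripSequence}} to every record whose stripped
#' sequence is still empty, using the grammar of the record's source
#' platform. Records that already carry a stripped sequence (some
#' platforms provide one) are left untouched.
#'
#' @param ps A \code{PeptideSet}.
#' @return The \code{PeptideSet} with \code{stripped_sequence} populated.
#' @export
processSequences <- function(ps) {
  stopifnot(is(ps, "PeptideSet"))
  rec <- ps@records
  todo <- which(is.na(rec$stripped_sequence) | rec$stripped_sequence == "")
  if (length(todo)) {
    grams <- lapply(rec$platform[todo],
                    function(p) resolveDialect(p)$grammar)
    rec$stripped_sequence[todo] <- mapply(
      function(s, g) scanModifiedSequence(s, g)$stripped,
      rec$modified_sequence[todo], grams, USE.NAMES = FALSE)
  }
  initialize(ps, records = rec)
}

#' Expand modifications into per-PTM positional records
#'
#' Every modification occurrence on every peptide becomes one row:
#' \code{ptm_position} is the 1-based index of the modified residue on the
#' stripped peptide (the count of residue letters preceding the annotation
#' in the modified string), with symbolic \code{"NTERM"}/\code{"CTERM"}
#' for terminal modifications. Mass-delta payloads are rendered as signed
#' two-decimal labels; records from the positional mzTab/mzIdentML readers
#' bypass grammar parsing and use their stored positions directly.
#' Unmodified peptides contribute zero rows. \code{multi_ptm} is
#' \code{TRUE} on every row of a peptide that contributed more than one.
#'
#' @param ps A \code{PeptideSet} (stripped sequences must be fillable).
#' @param ptm_table Optional \code{\link{ptmAnnotationTable}} controlling
#'   display labels and colors.
#' @return \code{DataFrame} with columns \code{record_id},
#'   \code{ptm_label}, \code{ptm_position}, \code{ptm_mass},
#'   \code{multi_ptm}, \code{display_label}, \code{display_color}.
#' @export
extractPtms <- function(ps, ptm_table = NULL) {
  stopifnot(is(ps, "PeptideSet"))
  if (!is.null(ptm_table) && anyDuplicated(ptm_table$ptm_key))
    stop("duplicate ptm_key in PTM annotation table")
  rec <- ps@records
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    plat <- rec$platform[i]
    spec <- resolveDialect(plat)
    if (identical(spec$grammar$payload, "positional")) {
      raw <- rec$ptm_raw[[i]]
      if (is.null(raw) || !nrow(raw)) next
      striplen <- nchar(rec$stripped_sequence[i])
      for (k in seq_len(nrow(raw))) {
        loc <- raw$location[k]
        pos <- if (loc == 0) "NTERM"
               else if (loc == striplen + 1L) "CTERM"
               else as.character(loc)
        lab <- if (!is.na(raw$name[k]) && nzchar(raw$name[k])) raw$name[k]
               else if (!is.na(raw$accession[k]) && nzchar(raw$accession[k]))
                 ptmLabel(raw$accession[k], "unimod")
               else ptmLabel(as.character(raw$mass[k]), "mass")
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = rec$record_id[i], ptm_label = lab,
          ptm_position = pos, ptm_mass = raw$mass[k],
          stringsAsFactors = FALSE)
      }
    } else {
      ms <- rec$modified_sequence[i]
      if (is.na(ms) || !nzchar(ms)) next
      sc <- scanModifiedSequence(ms, spec$grammar)
      for (a in sc$annotations) {
        pos <- if (!is.na(a$terminal)) a$terminal else as.character(a$position)
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = rec$record_id[i],
          ptm_label = ptmLabel(a$payload, spec$grammar$payload),
          ptm_position = pos,
          ptm_mass = ptmMass(a$payload, spec$grammar$payload),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- DataFrame(record_id = character(0), ptm_label = character(0),
                     ptm_position = character(0), ptm_mass = numeric(0),
                     multi_ptm = logical(0), display_label = character(0),
                     display_color = character(0))
    return(out)
  }
  tab <- do.call(rbind, rows)
  cnt <- table(tab$record_id)
  tab$multi_ptm <- as.vector(cnt[tab$record_id]) > 1L
  joined <- joinPtmTable(tab$ptm_label, tab$ptm_mass, ptm_table)
  tab$display_label <- joined$label
  tab$display_color <- joined$color
  ## positions must lie on the stripped peptide
  striplen <- setNames(nchar(rec$stripped_sequence), rec$record_id)
  num <- suppressWarnings(as.integer(tab$ptm_position))
  bad <- !is.na(num) & (num < 1L | num > striplen[tab$record_id])
  if (any(bad))
    stop("PTM position outside stripped peptide for record ",
         tab$record_id[which(bad)[1]])
  DataFrame(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
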