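#' Construct a PeptideSet in code
#'
#' Builds the canonical peptide table from a plain data.frame. Missing
#' canonical columns are filled with defaults (\code{NA} quant fields, an
#' autogenerated \code{record_id}). Any column not canonical and not
#' \code{platform}/\code{ptm_raw} is treated as a condition field.
#'
#' @param df data.frame with at least one of \code{modified_sequence} /
#'   \code{stripped_sequence}.
#' @param platform Platform whose modification grammar applies to
#'   \code{modified_sequence} (default \code{"maxquant"}).
#' @return A \code{PeptideSet}.
#' @export
peptideSet <- function(df, platform = "maxquant") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  canon <- c("record_id", "source_file", "modified_sequence",
             "stripped_sequence", "psm", "intensity", "area", "charge",
             "platform", "ptm_raw")
  if (is.null(df$record_id)) df$record_id <- sprintf("r%d", seq_len(n))
  if (is.null(df$source_file)) df$source_file <- "<memory>"
  if (is.null(df$modified_sequence)) df$modified_sequence <- NA_character_
  if (is.null(df$stripped_sequence)) df$stripped_sequence <- NA_character_
  for (qc in c("psm", "intensity", "area")) if (is.null(df[[qc]]))
    df[[qc]] <- NA_real_
  if (is.null(df$charge)) df$charge <- NA_integer_
  if (is.null(df$platform)) df$platform <- platform
  cond <- setdiff(colnames(df), canon)
  rec <- DataFrame(df[, intersect(canon, colnames(df)), drop = FALSE])
  for (cc in cond) rec[[cc]] <- df[[cc]]
  new("PeptideSet", records = rec, conditionFields = cond)
}

#' Construct a TargetSet
#'
#' @param sequences Named character vector or \code{AAStringSet} of target
#'   sequences (names are target ids); degenerate codes B/Z/X allowed.
#' @param meta Optional data.frame of per-target metadata with a
#'   \code{target_id} column (a \code{chain} column, e.g. HC/LC, is
#'   conventional for antibodies).
#' @param regions Optional data.frame of region annotations with columns
#'   \code{target_id}, \code{label}, \code{start}, \code{end},
#'   \code{category} (1-based inclusive coordinates).
#' @return A \code{TargetSet}.
#' @importFrom Biostrings AAStringSet width
#' @export
targetSet <- function(sequences, meta = NULL, regions = NULL) {
  if (is.character(sequences))
    sequences <- AAStringSet(toupper(sequences))
  if (is.null(meta))
    meta <- data.frame(target_id = names(sequences),
                       stringsAsFactors = FALSE)
  if (is.null(regions))
    regions <- data.frame(target_id = character(0), label = character(0),
                          start = integer(0), end = integer(0),
                          category = character(0), stringsAsFactors = FALSE)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  if (nrow(regions)) {
    regions$start <- as.integer(regions$start)
    regions$end <- as.integer(regions$end)
    if (is.null(regions$category)) regions$category <- "other"
  }
  new("TargetSet", sequences = sequences, targetMeta = DataFrame(meta),
      regions = DataFrame(regions))
}

#' Read target sequences from FASTA or TSV
#'
#' FASTA headers are parsed as \code{>target_id key=value ...}; a
#' \code{chain=} key populates the chain metadata. TSV files need columns
#' \code{target_id}, \code{sequence} and may carry \code{chain} plus
#' arbitrary metadata columns.
#'
#' @param path File path (.fasta/.fa/.faa or .tsv/.csv/.txt).
#' @param regions Optional path to a region annotation TSV (see
#'   \code{\link{readRegions}}).
#' @return A \code{TargetSet}.
#' @importFrom Biostrings readAAStringSet
#' @export
readTargets <- function(path, regions = NULL) {
  if (!file.exists(path)) stop("target file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fasta", "fa", "faa")) {
    seqs <- readAAStringSet(path)
    headers <- names(seqs)
    ids <- sub("\\s.*$", "", headers)
    kv <- regmatches(headers, gregexpr("\\b\\w+=\\S+", headers))
    meta <- data.frame(target_id = ids, stringsAsFactors = FALSE)
    chains <- vapply(kv, function(p) {
      hit <- grep("^chain=", p, value = TRUE)
      if (length(hit)) sub("^chain=", "", hit[1]) else NA_character_
    }, character(1))
    if (any(!is.na(chains))) meta$chain <- chains
    names(seqs) <- ids
    seqs <- AAStringSet(toupper(as.character(seqs)))
  } else {
    tab <- as.data.frame(data.table::fread(path, sep = "auto"))
    need <- c("target_id", "sequence")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
      stop("target table missing column(s): ", paste(miss, collapse = ", "))
    seqs <- AAStringSet(toupper(tab$sequence))
    names(seqs) <- tab$target_id
    meta <- tab[, setdiff(colnames(tab), "sequence"), drop = FALSE]
  }
  reg <- if (!is.null(regions)) readRegions(regions) else NULL
  targetSet(seqs, meta = meta, regions = reg)
}

#' Read region annotations from TSV/CSV
#'
#' @param path File with columns \code{target_id}, \code{label},
#'   \code{start}, \code{end}, \code{category} (category defaults to
#'   \code{"other"} when the column is absent).
#' @return data.frame of region annotations.
#' @export
readRegions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  tab <- as.data.frame(data.table::fread(path, sep = "auto"))
  need <- c("target_id", "label", "start", "end")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("region table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$category)) tab$category <- "other"
  tab
}

#' Write the canonical peptide table as TSV
#'
#' Fixed documented column order: record_id, source_file, condition
#' columns (lexicographic), modified_sequence, stripped_sequence, psm,
#' intensity, area, charge.
#'
#' @param ps A \code{PeptideSet}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writePeptideTable <- function(ps, path) {
  stopifnot(is(ps, "PeptideSet"))
  cols <- c("record_id", "source_file", sort(ps@conditionFields),
            "modified_sequence", "stripped_sequence", "psm", "intensity",
            "area", "charge")
  df <- as.data.frame(ps@records[, cols, drop = FALSE])
  data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Write a match table as TSV
#'
#' @param ms A \code{MatchSet}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeMatchTable <- function(ms, path) {
  stopifnot(is(ms, "MatchSet"))
  m <- as.data.frame(ms@matches)
  if (!is.null(m$region_labels))
    m$region_labels <- vapply(ms@matches$region_labels,
                              paste, character(1), collapse = ";")
  data.table::fwrite(m, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}
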