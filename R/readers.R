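## Readers: search-engine tabular outputs, mzTab and mzIdentML, all
## normalized into the canonical PeptideSet. Multiple files are read in
## one call, each carrying user-assigned condition labels (labels are
## supplied explicitly, never parsed from filenames).

## Assemble a records DataFrame with all canonical columns present.
buildRecords <- function(df, file_idx, path, platform, cond_labels,
                         ptm_raw = NULL) {
  n <- nrow(df)
  rec <- DataFrame(
    record_id = sprintf("f%d_r%d", file_idx, seq_len(n)),
    source_file = rep(path, n),
    modified_sequence = df$modified_sequence %||% rep(NA_character_, n),
    stripped_sequence = df$stripped_sequence %||% rep(NA_character_, n),
    psm = as.numeric(df$psm %||% rep(NA_real_, n)),
    intensity = as.numeric(df$intensity %||% rep(NA_real_, n)),
    area = as.numeric(df$area %||% rep(NA_real_, n)),
    charge = as.integer(df$charge %||% rep(NA_integer_, n)),
    platform = rep(platform, n))
  if (!is.null(ptm_raw)) rec$ptm_raw <- ptm_raw
  for (k in names(cond_labels)) rec[[k]] <- rep(cond_labels[[k]], n)
  rec
}

bindRecordSets <- function(recs, cond_fields) {
  allcols <- unique(unlist(lapply(recs, colnames)))
  recs <- lapply(recs, function(r) {
    for (cc in setdiff(allcols, colnames(r))) r[[cc]] <- NA
    r[, allcols, drop = FALSE]
  })
  rec <- do.call(rbind, recs)
  new("PeptideSet", records = rec, conditionFields = cond_fields)
}

#' Read search-engine result files into a PeptideSet
#'
#' Parses one or more files written by a supported platform and
#' concatenates them into the canonical peptide table. Each file gets its
#' own condition labels (e.g. donor, antibody, timepoint) attached to
#' every row. Field separators are sniffed from the file unless given.
#' Quantitative columns are optional in every dialect: absent values stay
#' \code{NA}, never zero.
#'
#' @param paths Character vector of file paths.
#' @param platform One of \code{listPlatforms()}.
#' @param condition_labels Optional list, one named list per path, e.g.
#'   \code{list(list(donor = "D1"), list(donor = "D2"))}.
#' @param dialect_overrides Optional partial dialect (list with
#'   \code{column_map} and/or \code{grammar} entries) patching the
#'   built-in spec, e.g. for renamed columns.
#' @param sep Explicit field separator overriding sniffing.
#' @return A \code{PeptideSet}; row order within each file is preserved.
#' @export
readResults <- function(paths, platform, condition_labels = NULL,
                        dialect_overrides = NULL, sep = NULL) {
  spec <- resolveDialect(platform, dialect_overrides)
  if (!is.null(condition_labels) &&
        length(condition_labels) != length(paths))
    stop("condition_labels must have one entry per path")
  if (platform == "mztab")
    return(readStandardMulti(paths, condition_labels, readMzTabRecords))
  if (platform == "mzid")
    return(readStandardMulti(paths, condition_labels, readMzidRecords))
  recs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    path <- paths[i]
    if (!file.exists(path) || file.size(path) == 0)
      stop("cannot read input file (missing or empty): ", path)
    tab <- tryCatch(
      as.data.frame(data.table::fread(path, sep = sep %||% "auto")),
      error = function(e) stop("cannot read input file: ", path, " (",
                               conditionMessage(e), ")"))
    cm <- spec$column_map
    seq_fields <- intersect(c("modified_sequence", "stripped_sequence"),
                            names(cm))
    present <- vapply(seq_fields, function(f) cm[[f]] %in% colnames(tab),
                      logical(1))
    if (!any(present))
      stop(sprintf("schema error in '%s': missing mandatory column(s) %s",
                   path,
                   paste(sprintf("'%s'", unlist(cm[seq_fields])),
                         collapse = " / ")))
    df <- data.frame(row.names = seq_len(nrow(tab)))
    for (f in names(cm)) {
      if (cm[[f]] %in% colnames(tab)) df[[f]] <- tab[[cm[[f]]]]
    }
    for (qc in c("psm", "intensity", "area"))
      if (!is.null(df[[qc]]) && any(!is.na(df[[qc]]) & df[[qc]] < 0))
        stop(sprintf("negative %s value in '%s'", qc, path))
    cl <- if (is.null(condition_labels)) list() else condition_labels[[i]]
    recs[[i]] <- buildRecords(df, i, path, platform, cl)
  }
  cond_fields <- sort(unique(unlist(lapply(condition_labels, names))))
  bindRecordSets(recs, cond_fields %||% character(0))
}

readStandardMulti <- function(paths, condition_labels, reader) {
  recs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    cl <- if (is.null(condition_labels)) list() else condition_labels[[i]]
    recs[[i]] <- reader(paths[i], i, cl)
  }
  cond_fields <- sort(unique(unlist(lapply(condition_labels, names))))
  bindRecordSets(recs, cond_fields %||% character(0))
}

## --- mzTab ---------------------------------------------------------------

## Parse "{position}-{accession}" modification strings, e.g.
## "3-UNIMOD:21" or "5-CHEMMOD:+79.97"; "null"/"" mean unmodified.
parseMzTabMods <- function(s) {
  empty <- data.frame(location = integer(0), mass = numeric(0),
                      name = character(0), accession = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(s) || s %in% c("", "null")) return(empty)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*(\\d+)-(.+)$", parts))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("malformed mzTab modification string: ", s)
  loc <- vapply(m, function(g) as.integer(g[2]), integer(1))
  acc <- vapply(m, function(g) g[3], character(1))
  mass <- ifelse(grepl("^CHEMMOD:", acc),
                 suppressWarnings(as.numeric(sub("^CHEMMOD:", "", acc))),
                 NA_real_)
  data.frame(location = loc, mass = mass, name = NA_character_,
             accession = ifelse(grepl("^CHEMMOD:", acc), NA_character_, acc),
             stringsAsFactors = FALSE)
}

readMzTabRecords <- function(path, file_idx, cond_labels) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("cannot read input file (missing or empty): ", path)
  lines <- readLines(path, warn = FALSE)
  prefix <- sub("\t.*$", "", lines)
  hdr_i <- which(prefix %in% c("PSH", "PEH"))
  row_tag <- c(PSH = "PSM", PEH = "PEP")
  if (!length(hdr_i))
    stop("schema error in '", path, "': no PSM/PEP section header")
  hdr_i <- hdr_i[1]
  tag <- row_tag[[prefix[hdr_i]]]
  early <- which(prefix == tag & seq_along(prefix) < hdr_i)
  if (length(early))
    stop(sprintf("schema error in '%s': %s row at line %d before section header",
                 path, tag, early[1]))
  header <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]][-1]
  rows_i <- which(prefix == tag)
  if (!length(rows_i))
    stop("schema error in '", path, "': section '", tag, "' has no rows")
  cells <- lapply(rows_i, function(j) {
    v <- strsplit(lines[j], "\t", fixed = TRUE)[[1]][-1]
    if (length(v) != length(header))
      stop(sprintf("schema error in '%s': line %d has %d fields, header has %d",
                   path, j, length(v), length(header)))
    v
  })
  tab <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  colnames(tab) <- header
  if (!"sequence" %in% header)
    stop("schema error in '", path, "': missing mandatory column 'sequence'")
  num <- function(col) if (col %in% header)
    suppressWarnings(as.numeric(ifelse(tab[[col]] == "null", NA,
                                       tab[[col]]))) else NULL
  df <- data.frame(stripped_sequence = toupper(tab$sequence),
                   stringsAsFactors = FALSE)
  df$psm <- num("opt_global_psm_count")
  df$intensity <- num("opt_global_intensity")
  df$area <- num("opt_global_area")
  df$charge <- num("charge")
  mods <- if ("modifications" %in% header) tab$modifications
          else rep("null", nrow(tab))
  ptm_raw <- lapply(mods, parseMzTabMods)
  rec <- buildRecords(df, file_idx, path, "mztab", cond_labels,
                      ptm_raw = ptm_raw)
  rec$modifications_raw <- mods
  rec
}

#' Read an mzTab file
#'
#' Builds peptide records from the PSM (or PEP) section. Modification
#' strings (\code{"3-UNIMOD:21"} position-accession pairs, mzTab
#' \code{"null"} convention for none) are retained verbatim in a
#' \code{modifications_raw} column and parsed into positional PTM entries
#' consumed by \code{\link{extractPtms}}.
#'
#' @param path mzTab file path.
#' @param condition_labels Optional named list of condition values for
#'   this file.
#' @return A \code{PeptideSet}.
#' @export
readMzTab <- function(path, condition_labels = NULL) {
  readResults(path, "mztab",
              if (is.null(condition_labels)) NULL else list(condition_labels))
}

## --- mzIdentML -----------------------------------------------------------

readMzidRecords <- function(path, file_idx, cond_labels) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("cannot read input file (missing or empty): ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("mzIdentML XML parse failure in '",
                                           path, "': ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  peps <- xml2::xml_find_all(doc, ".//SequenceCollection/Peptide")
  if (!length(peps))
    stop("cross-reference error in '", path,
         "': empty SequenceCollection (no Peptide elements)")
  pep_ids <- xml2::xml_attr(peps, "id")
  pep_seq <- vapply(peps, function(p)
    xml2::xml_text(xml2::xml_find_first(p, "./PeptideSequence")),
    character(1))
  pep_mods <- lapply(peps, function(p) {
    mods <- xml2::xml_find_all(p, "./Modification")
    if (!length(mods))
      return(data.frame(location = integer(0), mass = numeric(0),
                        name = character(0), accession = character(0),
                        stringsAsFactors = FALSE))
    data.frame(
      location = as.integer(xml2::xml_attr(mods, "location")),
      mass = as.numeric(xml2::xml_attr(mods, "monoisotopicMassDelta")),
      name = vapply(mods, function(m) {
        cv <- xml2::xml_find_first(m, "./cvParam")
        if (inherits(cv, "xml_missing")) NA_character_
        else xml2::xml_attr(cv, "name")
      }, character(1)),
      accession = vapply(mods, function(m) {
        cv <- xml2::xml_find_first(m, "./cvParam")
        if (inherits(cv, "xml_missing")) NA_character_
        else xml2::xml_attr(cv, "accession")
      }, character(1)),
      stringsAsFactors = FALSE)
  })
  names(pep_mods) <- pep_ids
  items <- xml2::xml_find_all(
    doc, ".//SpectrumIdentificationResult/SpectrumIdentificationItem")
  refs <- xml2::xml_attr(items, "peptide_ref")
  unknown <- setdiff(refs, pep_ids)
  if (length(unknown))
    stop("cross-reference error in '", path,
         "': peptide_ref not resolvable: ", unknown[1])
  idx <- match(refs, pep_ids)
  userNum <- function(item, nm) {
    up <- xml2::xml_find_first(item, sprintf("./userParam[@name='%s']", nm))
    if (inherits(up, "xml_missing")) NA_real_
    else as.numeric(xml2::xml_attr(up, "value"))
  }
  df <- data.frame(stripped_sequence = pep_seq[idx],
                   stringsAsFactors = FALSE)
  df$charge <- as.integer(xml2::xml_attr(items, "chargeState"))
  df$psm <- vapply(items, userNum, numeric(1), nm = "psm_count")
  df$intensity <- vapply(items, userNum, numeric(1), nm = "intensity")
  df$area <- vapply(items, userNum, numeric(1), nm = "area")
  buildRecords(df, file_idx, path, "mzid", cond_labels,
               ptm_raw = pep_mods[idx])
}

#' Read an mzIdentML file
#'
#' One record per SpectrumIdentificationItem; Modification elements
#' (location, monoisotopic mass delta, cvParam name) are carried along as
#' positional PTM entries for \code{\link{extractPtms}}. Location 0 maps
#' to the peptide N-terminus, length+1 to the C-terminus.
#'
#' @inheritParams readMzTab
#' @return A \code{PeptideSet}.
#' @export
readMzid <- function(path, condition_labels = NULL) {
  readResults(path, "mzid",
              if (is.null(condition_labels)) NULL else list(condition_labels))
}
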