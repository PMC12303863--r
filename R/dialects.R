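## Dialect registry: each supported search engine's output schema is data,
## not code. A DialectSpec names the source columns behind each canonical
## field and describes the modification notation grammar, so readers and
## the fixture serializers share one definition and schema drift is patched
## with dialectOverrides rather than code changes.

SUPPORTED_PLATFORMS <- c("peaks", "spectronaut", "msfragger", "comet",
                         "diann", "skyline", "maxquant", "mztab", "mzid")

#' Construct a dialect specification
#'
#' A DialectSpec describes how one search engine's tabular output maps onto
#' the canonical peptide record: which source column holds each canonical
#' field, and how modifications are written inside the peptide string.
#'
#' @param platform_id Platform identifier string.
#' @param column_map Named list mapping canonical fields
#'   (\code{modified_sequence}, \code{stripped_sequence}, \code{psm},
#'   \code{intensity}, \code{area}, \code{charge}, \code{protein_hint})
#'   to source column names. Sequence fields are mandatory on read when
#'   mapped alone; quantitative fields are always optional.
#' @param grammar Modification grammar: a list with \code{open} and
#'   \code{close} delimiter characters, \code{payload} kind
#'   (\code{"mass"}, \code{"name"} or \code{"unimod"}), logical
#'   \code{flanking} (peptide printed as \code{"K.PEPTIDE.R"}),
#'   \code{terminal} marker character (e.g. \code{"_"}) or \code{NA}, and
#'   logical \code{nc_markers} (lowercase \code{n}/\code{c} terminal
#'   prefixes as printed by MSFragger).
#' @param sep Field separator of the native file ("\\t" or ",");
#'   \code{NA} means sniff from the header line.
#' @param ext Preferred file extension for serialized fixtures.
#' @return A list of class \code{"DialectSpec"}.
#' @export
dialectSpec <- function(platform_id, column_map, grammar,
                        sep = "\t", ext = "tsv") {
  stopifnot(is.character(platform_id), length(platform_id) == 1L)
  seq_fields <- intersect(c("modified_sequence", "stripped_sequence"),
                          names(column_map))
  if (!length(seq_fields))
    stop("DialectSpec '", platform_id,
         "' must map at least one sequence field")
  g <- modifyList(list(open = "(", close = ")", payload = "name",
                       flanking = FALSE, terminal = NA_character_,
                       nc_markers = FALSE), grammar)
  if (identical(g$open, g$close))
    stop("modification grammar opener and closer must differ")
  structure(list(platform_id = platform_id, column_map = column_map,
                 grammar = g, sep = sep, ext = ext),
            class = "DialectSpec")
}

#' Built-in dialect registry
#'
#' Encodes the documented column names of each supported tool's summarized
#' output (PEAKS peptide export, Spectronaut report, MSFragger/FragPipe
#' psm.tsv, Comet txt, DIA-NN report.tsv, Skyline peptide report, MaxQuant
#' evidence.txt). Tool schemas drift between versions; patch renamed
#' columns at read time with \code{dialect_overrides} rather than editing
#' the registry. Where a tool's stock output defines no column for a
#' canonical quantitative field, the registry names an optional extension
#' column so round-trip fixtures can carry the value; such columns are
#' simply absent in real exports and the field stays \code{NA}.
#'
#' @return Named list of \code{DialectSpec}s, one per supported platform
#'   (the standardized \code{mztab}/\code{mzid} formats have dedicated
#'   readers and carry a positional modification grammar).
#' @export
builtinDialects <- function() {
  list(
    peaks = dialectSpec("peaks",
      list(modified_sequence = "Peptide", psm = "#Spec", area = "Area",
           intensity = "Intensity", charge = "Z",
           protein_hint = "Accession"),
      list(open = "(", close = ")", payload = "mass"),
      sep = ",", ext = "csv"),
    spectronaut = dialectSpec("spectronaut",
      list(modified_sequence = "EG.ModifiedSequence",
           stripped_sequence = "PEP.StrippedSequence",
           intensity = "FG.Quantity", psm = "PEP.RunEvidenceCount",
           area = "FG.TotalPeakArea", charge = "FG.Charge",
           protein_hint = "PG.ProteinAccessions"),
      list(open = "[", close = "]", payload = "name", terminal = "_")),
    msfragger = dialectSpec("msfragger",
      list(stripped_sequence = "Peptide",
           modified_sequence = "Modified Peptide",
           intensity = "Intensity", psm = "Spectral Count",
           area = "Area", charge = "Charge", protein_hint = "Protein"),
      list(open = "[", close = "]", payload = "mass", nc_markers = TRUE)),
    comet = dialectSpec("comet",
      list(stripped_sequence = "plain_peptide",
           modified_sequence = "modified_peptide",
           psm = "spectral_count", intensity = "intensity", area = "area",
           charge = "charge", protein_hint = "protein"),
      list(open = "[", close = "]", payload = "mass", flanking = TRUE)),
    diann = dialectSpec("diann",
      list(stripped_sequence = "Stripped.Sequence",
           modified_sequence = "Modified.Sequence",
           intensity = "Precursor.Quantity", psm = "MS2.Count",
           area = "Precursor.Area", charge = "Precursor.Charge",
           protein_hint = "Protein.Ids"),
      list(open = "(", close = ")", payload = "unimod")),
    skyline = dialectSpec("skyline",
      list(stripped_sequence = "Peptide Sequence",
           modified_sequence = "Peptide Modified Sequence",
           area = "Total Area", intensity = "Total Height",
           psm = "Spectral Count", charge = "Precursor Charge",
           protein_hint = "Protein Name"),
      list(open = "[", close = "]", payload = "mass"),
      sep = ",", ext = "csv"),
    maxquant = dialectSpec("maxquant",
      list(stripped_sequence = "Sequence",
           modified_sequence = "Modified sequence",
           intensity = "Intensity", psm = "MS/MS count",
           area = "Area", charge = "Charge", protein_hint = "Proteins"),
      list(open = "(", close = ")", payload = "name", terminal = "_")),
    mztab = dialectSpec("mztab",
      list(stripped_sequence = "sequence", psm = "opt_global_psm_count",
           intensity = "opt_global_intensity", area = "opt_global_area",
           charge = "charge", protein_hint = "accession"),
      list(payload = "positional"), ext = "mztab"),
    mzid = dialectSpec("mzid",
      list(stripped_sequence = "PeptideSequence", psm = "psm",
           intensity = "intensity", area = "area",
           charge = "chargeState", protein_hint = "protein"),
      list(payload = "positional"), ext = "mzid")
  )
}

#' @rdname builtinDialects
#' @export
listPlatforms <- function() SUPPORTED_PLATFORMS

## Resolve a platform name (+ optional partial overrides) to a DialectSpec.
resolveDialect <- function(platform, dialect_overrides = NULL) {
  if (!is.character(platform) || length(platform) != 1L ||
        !platform %in% SUPPORTED_PLATFORMS)
    stop("unsupported platform: ", paste(platform, collapse = ","),
         " (supported: ", paste(SUPPORTED_PLATFORMS, collapse = ", "), ")")
  spec <- builtinDialects()[[platform]]
  if (!is.null(dialect_overrides)) {
    if (!is.null(dialect_overrides$column_map))
      spec$column_map <- modifyList(spec$column_map,
                                    dialect_overrides$column_map)
    if (!is.null(dialect_overrides$grammar))
      spec$grammar <- modifyList(spec$grammar, dialect_overrides$grammar)
    for (f in intersect(c("sep", "ext"), names(dialect_overrides)))
      spec[[f]] <- dialect_overrides[[f]]
  }
  spec
}
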