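## Synthetic ground-truthed fixtures: target sequences with planted
## regions, and search-result files in every supported dialect whose
## peptides are true substrings of the target. The serializers share the
## DialectSpec registry with the readers, so a schema change breaks both
## sides loudly. One integer seed drives a single pseudo-random stream;
## no binary files are ever written.

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Small catalog of common modifications used by the generator.
modCatalog <- function() {
  data.frame(
    name = c("Phospho (STY)", "Oxidation (M)", "Acetyl (K)",
             "Carbamidomethyl (C)", "Deamidation (NQ)"),
    mass = c(79.9663, 15.9949, 42.0106, 57.0215, 0.9840),
    unimod = c(21L, 35L, 1L, 4L, 7L),
    stringsAsFactors = FALSE)
}

withSeed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

## Stream versions (no seeding) used inside generateFixture so one seed
## drives everything.
targetFromStream <- function(length, n_regions, degenerate_fraction) {
  if (length < 10) stop("target length must be >= 10")
  if (n_regions < 0 || n_regions > length / 5)
    stop("infeasible region packing: n_regions must be <= length/5")
  if (degenerate_fraction < 0 || degenerate_fraction > 1)
    stop("degenerate_fraction must be in [0, 1]")
  seq <- sample(STANDARD_AA, length, replace = TRUE)
  n_deg <- round(degenerate_fraction * length)
  if (n_deg > 0) {
    at <- sample.int(length, n_deg)
    seq[at] <- sample(c("B", "Z", "X"), n_deg, replace = TRUE)
  }
  regions <- NULL
  if (n_regions > 0) {
    ## one region per equal-width block keeps intervals disjoint
    block <- floor(length / n_regions)
    cats <- rep_len(c("domain", "cdr", "mutation", "other"), n_regions)
    rows <- lapply(seq_len(n_regions), function(k) {
      lo <- (k - 1L) * block + 1L
      hi <- min(k * block, length)
      w <- sample(seq_len(max(1L, min(hi - lo, 8L))), 1L)
      st <- lo + sample.int(hi - lo - w + 2L, 1L) - 1L
      data.frame(target_id = "T1", label = sprintf("R%d", k),
                 start = st, end = st + w - 1L, category = cats[k],
                 stringsAsFactors = FALSE)
    })
    regions <- do.call(rbind, rows)
  }
  targetSet(setNames(paste(seq, collapse = ""), "T1"), regions = regions)
}

#' Generate a synthetic target with region annotations
#'
#' Uniform random sequence over the 20 standard residues with a stated
#' fraction of positions replaced by the degenerate codes B/Z/X, and
#' non-overlapping labelled regions. Fully determined by the seed.
#'
#' @param length Target length (>= 10).
#' @param n_regions Number of disjoint regions (<= length/5).
#' @param degenerate_fraction Fraction of positions replaced by B/Z/X.
#' @param seed Integer seed.
#' @return A \code{TargetSet} with one target \code{"T1"}.
#' @export
generateTarget <- function(length, n_regions = 0, degenerate_fraction = 0,
                           seed = 1) {
  withSeed(seed, targetFromStream(length, n_regions, degenerate_fraction))
}

peptidesFromStream <- function(target, n_peptides, mod_rate) {
  tseq <- as.character(targetSequences(target))[[1]]
  L <- nchar(tseq)
  cat_ <- modCatalog()
  rows <- vector("list", n_peptides)
  for (i in seq_len(n_peptides)) {
    len <- sample(8:min(15, L), 1L)
    st <- sample.int(L - len + 1L, 1L)
    pep <- substr(tseq, st, st + len - 1L)
    mods <- data.frame(position = integer(0), name = character(0),
                       mass = numeric(0), unimod = integer(0),
                       stringsAsFactors = FALSE)
    if (stats::runif(1) < mod_rate) {
      k <- sample(1:2, 1L)
      pos <- sort(sample.int(len, min(k, len)))
      pick <- sample.int(nrow(cat_), length(pos), replace = TRUE)
      mods <- data.frame(position = pos, name = cat_$name[pick],
                         mass = cat_$mass[pick], unimod = cat_$unimod[pick],
                         stringsAsFactors = FALSE)
    }
    rows[[i]] <- list(sequence = pep, start = st, end = st + len - 1L,
                      mods = mods,
                      psm = sample(1:5, 1L),
                      intensity = round(10^stats::runif(1, 4, 8)),
                      area = round(10^stats::runif(1, 3, 7)),
                      charge = sample(2:4, 1L))
  }
  rows
}

## Render a stripped sequence + modification table in a dialect's grammar.
renderModified <- function(seq, mods, platform, prev_aa = "-",
                           next_aa = "-") {
  g <- resolveDialect(platform)$grammar
  payload <- function(k) {
    switch(g$payload,
           mass = if (platform == "peaks") sprintf("%+.2f", mods$mass[k])
                  else if (platform == "skyline")
                    sprintf("%+.4f", mods$mass[k])
                  else sprintf("%.4f", mods$mass[k]),
           unimod = sprintf("UniMod:%d", mods$unimod[k]),
           name = mods$name[k])
  }
  chars <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (i in seq_along(chars)) {
    out <- c(out, chars[i])
    hit <- which(mods$position == i)
    for (k in hit) out <- c(out, paste0(g$open, payload(k), g$close))
  }
  s <- paste(out, collapse = "")
  if (!is.na(g$terminal)) s <- paste0(g$terminal, s, g$terminal)
  if (isTRUE(g$flanking)) s <- paste0(prev_aa, ".", s, ".", next_aa)
  s
}

writeTabularFixture <- function(platform, peps, target, path) {
  spec <- resolveDialect(platform)
  cm <- spec$column_map
  tseq <- as.character(targetSequences(target))[[1]]
  L <- nchar(tseq)
  n <- length(peps)
  tab <- data.frame(row.names = seq_len(n))
  get_mod <- vapply(peps, function(p) {
    prev <- if (p$start > 1) substr(tseq, p$start - 1, p$start - 1) else "-"
    nxt <- if (p$end < L) substr(tseq, p$end + 1, p$end + 1) else "-"
    if (platform == "msfragger" && !nrow(p$mods)) ""
    else renderModified(p$sequence, p$mods, platform, prev, nxt)
  }, character(1))
  vals <- list(
    modified_sequence = get_mod,
    stripped_sequence = vapply(peps, `[[`, character(1), "sequence"),
    psm = vapply(peps, `[[`, numeric(1), "psm"),
    intensity = vapply(peps, `[[`, numeric(1), "intensity"),
    area = vapply(peps, `[[`, numeric(1), "area"),
    charge = vapply(peps, `[[`, numeric(1), "charge"),
    protein_hint = rep(targetIds(target)[1], n))
  for (f in names(cm)) if (f %in% names(vals)) tab[[cm[[f]]]] <- vals[[f]]
  ## a few tool-typical extra columns the readers ignore
  tab[["scan"]] <- seq_len(n)
  tab[["score"]] <- round(stats::runif(n), 4)
  data.table::fwrite(tab, path, sep = spec$sep, quote = FALSE)
  path
}

writeMzTabFixture <- function(peps, path) {
  n <- length(peps)
  hdr <- c("sequence", "PSM_ID", "accession", "unique", "database",
           "database_version", "search_engine",
           "best_search_engine_score[1]", "modifications",
           "retention_time", "charge", "exp_mass_to_charge",
           "calc_mass_to_charge", "spectra_ref", "pre", "post",
           "start", "end", "opt_global_psm_count",
           "opt_global_intensity", "opt_global_area")
  lines <- c(
    "MTD\tmzTab-version\t1.0.0",
    "MTD\tmzTab-mode\tSummary",
    "MTD\tmzTab-type\tIdentification",
    "MTD\tdescription\tsynthetic fixture",
    "",
    paste(c("PSH", hdr), collapse = "\t"))
  for (i in seq_len(n)) {
    p <- peps[[i]]
    mods <- if (nrow(p$mods))
      paste(sprintf("%d-UNIMOD:%d", p$mods$position, p$mods$unimod),
            collapse = ",")
    else "null"
    row <- c(p$sequence, sprintf("PSM_%d", i), "T1", "1", "synthetic",
             "1.0", "[MS, MS:1001207, synthetic, ]", "0.0", mods,
             "100.0", p$charge, "500.0", "500.0",
             sprintf("ms_run[1]:index=%d", i), "-", "-", p$start, p$end,
             p$psm, p$intensity, p$area)
    lines <- c(lines, paste(c("PSM", row), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

writeMzidFixture <- function(peps, path) {
  n <- length(peps)
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  pep_xml <- vapply(seq_len(n), function(i) {
    p <- peps[[i]]
    mods <- if (nrow(p$mods))
      paste(vapply(seq_len(nrow(p$mods)), function(k) sprintf(
        paste0('      <Modification location="%d" ',
               'monoisotopicMassDelta="%.4f">\n',
               '        <cvParam cvRef="UNIMOD" accession="UNIMOD:%d" ',
               'name="%s"/>\n      </Modification>'),
        p$mods$position[k], p$mods$mass[k], p$mods$unimod[k],
        esc(p$mods$name[k])), character(1)), collapse = "\n")
    else ""
    sprintf(paste0('    <Peptide id="pep_%d">\n',
                   '      <PeptideSequence>%s</PeptideSequence>\n%s',
                   '    </Peptide>'),
            i, p$sequence, if (nzchar(mods)) paste0(mods, "\n") else "")
  }, character(1))
  sii_xml <- vapply(seq_len(n), function(i) {
    p <- peps[[i]]
    sprintf(paste0(
      '      <SpectrumIdentificationResult id="SIR_%d" ',
      'spectrumID="index=%d">\n',
      '        <SpectrumIdentificationItem id="SII_%d" rank="1" ',
      'passThreshold="true" peptide_ref="pep_%d" chargeState="%d" ',
      'experimentalMassToCharge="500.0" calculatedMassToCharge="500.0">\n',
      '          <userParam name="psm_count" value="%d"/>\n',
      '          <userParam name="intensity" value="%d"/>\n',
      '          <userParam name="area" value="%d"/>\n',
      '        </SpectrumIdentificationItem>\n',
      '      </SpectrumIdentificationResult>'),
      i, i, i, i, p$charge, p$psm, p$intensity, p$area)
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<MzIdentML xmlns="http://psidev.info/psi/pi/mzIdentML/1.2" ',
    'version="1.2.0" id="synthetic">\n',
    '  <SequenceCollection>\n',
    paste(pep_xml, collapse = "\n"), "\n",
    '  </SequenceCollection>\n',
    '  <DataCollection>\n    <AnalysisData>\n',
    '      <SpectrumIdentificationList id="SIL_1">\n',
    paste(sii_xml, collapse = "\n"), "\n",
    '      </SpectrumIdentificationList>\n',
    '    </AnalysisData>\n  </DataCollection>\n',
    '</MzIdentML>\n')
  cat(doc, file = path)
  path
}

#' Generate a ground-truthed fixture file in a platform's dialect
#'
#' Peptides are sampled as true substrings of a generated (or supplied)
#' target, decorated with grammar-valid modifications at the given rate,
#' and serialized in the platform's native dialect. The returned ground
#' truth records the planted sequences, match coordinates, modification
#' positions and quantities, and is also written as a JSON sidecar next
#' to the file. Identical seeds yield byte-identical files.
#'
#' @param platform One of \code{listPlatforms()}.
#' @param n_peptides Number of peptide rows (>= 1).
#' @param mod_rate Probability that a peptide carries 1-2 modifications.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param target Optional \code{TargetSet} to plant peptides in; default
#'   is a fresh 120-residue target with 3 regions derived from the seed.
#' @return List with \code{path}, \code{ground_truth} (list of per-peptide
#'   truths), \code{target}, and \code{sidecar} (JSON path).
#' @export
generateFixture <- function(platform, n_peptides, mod_rate = 0.3, seed = 1,
                            dir = tempdir(), target = NULL) {
  spec <- resolveDialect(platform)
  if (n_peptides < 1) stop("n_peptides must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(seed, {
    if (is.null(target))
      target <- targetFromStream(120L, 3L, 0)
    peps <- peptidesFromStream(target, n_peptides, mod_rate)
    path <- file.path(dir, sprintf("%s_fixture.%s", platform, spec$ext))
    if (platform == "mztab") writeMzTabFixture(peps, path)
    else if (platform == "mzid") writeMzidFixture(peps, path)
    else writeTabularFixture(platform, peps, target, path)
    gt <- list(platform = platform, seed = seed,
               target_id = targetIds(target)[1],
               target_sequence = as.character(targetSequences(target))[[1]],
               regions = as.data.frame(targetRegions(target)),
               peptides = peps)
    sidecar <- paste0(path, ".ground_truth.json")
    jsonlite::write_json(
      list(platform = platform, seed = seed,
           target_sequence = gt$target_sequence,
           peptides = lapply(peps, function(p)
             list(sequence = p$sequence, start = p$start, end = p$end,
                  psm = p$psm, intensity = p$intensity, area = p$area,
                  charge = p$charge, mods = p$mods))),
      sidecar, auto_unbox = TRUE, digits = NA)
    list(path = path, ground_truth = gt, target = target, sidecar = sidecar)
  })
}

#' Generate a complete fixture project (all dialects share one truth)
#'
#' Serializes one ground-truth peptide set into every supported dialect,
#' for cross-dialect consistency checks and end-to-end pipeline runs.
#'
#' @inheritParams generateFixture
#' @param platforms Platforms to emit (default: all supported).
#' @return List with \code{files} (named paths), \code{ground_truth},
#'   \code{target}, and \code{target_path}/\code{region_path} (TSVs).
#' @export
generateFixtureProject <- function(n_peptides = 10, mod_rate = 0.3,
                                   seed = 1, dir = tempdir(),
                                   platforms = listPlatforms()) {
  base <- generateFixture(platforms[1], n_peptides, mod_rate, seed,
                          dir = dir)
  target <- base$target
  peps <- base$ground_truth$peptides
  files <- setNames(vector("list", length(platforms)), platforms)
  files[[platforms[1]]] <- base$path
  for (p in setdiff(platforms, platforms[1])) {
    spec <- resolveDialect(p)
    path <- file.path(dir, sprintf("%s_fixture.%s", p, spec$ext))
    if (p == "mztab") writeMzTabFixture(peps, path)
    else if (p == "mzid") writeMzidFixture(peps, path)
    else withSeed(seed + 1L, writeTabularFixture(p, peps, target, path))
    files[[p]] <- path
  }
  tpath <- file.path(dir, "targets.tsv")
  tdf <- data.frame(target_id = targetIds(target),
                    sequence = as.character(targetSequences(target)),
                    stringsAsFactors = FALSE)
  data.table::fwrite(tdf, tpath, sep = "\t", quote = FALSE)
  rpath <- file.path(dir, "regions.tsv")
  data.table::fwrite(as.data.frame(targetRegions(target)), rpath,
                     sep = "\t", quote = FALSE)
  list(files = files, ground_truth = base$ground_truth, target = target,
       target_path = tpath, region_path = rpath)
}
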