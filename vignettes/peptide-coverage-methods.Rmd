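---
title: "Methods: degeneracy-aware peptide mapping and per-residue roll-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degeneracy-aware peptide mapping and per-residue roll-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PepCoverage)
```

## The problem

Bottom-up proteomics identifies peptides, not proteins. Once a search
engine has assigned spectra to peptide sequences, many questions —
which regions of an antibody are presented on MHC-II across donors,
whether a point mutation creates a new presented region, how two search
engines disagree on one protein — reduce to the same operation: place
every identified peptide on its target sequence and aggregate
per-residue evidence per experimental condition. PepCoverage implements
that operation end to end. This vignette records the model, the
conventions, and the design decisions, so that results are
interpretable without reading the source.

## Canonical peptide records

Every supported input (seven engine dialects plus mzTab and mzIdentML)
is normalized to one row per identified peptide occurrence with the
fields `modified_sequence`, `stripped_sequence`, `psm`, `intensity`,
`area`, `charge`, plus free-form condition columns supplied by the user
at read time. Three conventions matter:

* **Dialects are data.** Each engine's schema lives in a registry entry
  (`builtinDialects()`) mapping canonical fields to that tool's
  documented column names and describing its modification grammar.
  Tool schemas drift between releases, so renamed columns are patched
  with `dialect_overrides` at read time instead of code changes. Where
  a stock export defines no column for a quantitative field, the
  registry names an optional extension column; in real exports it is
  simply absent and the field stays `NA`.
* **Absent is not zero.** Missing `psm`/`intensity`/`area` values stay
  `NA`; the quantification step decides their treatment (weight 1 for
  missing PSM counts, contribution 0 with a warning for missing
  intensities). Coercing to 0 at read time would silently conflate
  "not measured" with "measured as nothing".
* **Labels are explicit.** Condition labels are passed per file at read
  time, never parsed from filenames; a run is fully described by its
  configuration.

mzIdentML is parsed as a whole document (DOM) with `xml2`; files of the
size this package targets (summarized identification lists, not raw
spectra) fit comfortably in memory.

## Stripping and PTM extraction

A modification grammar is four facts: the annotation delimiters (with
nesting, for names like `(Phospho (S))`), the payload kind (mass delta,
modification name, or UniMod accession), whether flanking residues are
printed (`K.PEPTIDE.R`), and the terminal-marker convention (enclosing
underscores, or MSFragger-style lowercase `n`/`c` prefixes). One
scanner walks the string, removes flanks and terminals, skips balanced
annotations, and counts residue letters. That count at the moment an
annotation is seen *is* the modification's 1-based position on the
stripped peptide.

Conventions chosen here:

* Terminal modifications get symbolic positions `NTERM`/`CTERM` rather
  than 0/length+1, avoiding coordinate ambiguity when projecting onto
  target coordinates. An annotation before the first residue in a
  grammar with no terminal convention is an error, not a guess.
* Mass-delta payloads are rendered as signed two-decimal labels
  (`+79.97`) for display and joined against user PTM tables within a
  0.01 Da tolerance (both overridable). Sources print the same
  modification as `79.9663`, `+79.97` or `[+80]`; a canonical rendering
  plus tolerance joining is the smallest rule that unifies them. This
  two-decimal canonicalization is this package's convention, chosen
  because it is unambiguous at typical reporting precision.
* mzTab (`3-UNIMOD:21` strings) and mzIdentML (`Modification` elements)
  already encode positions; they bypass grammar parsing entirely.
* PTM keys absent from the user table keep their raw label and draw a
  color from a fixed cycling palette, so an incomplete table degrades
  gracefully.
* Each modification occurrence becomes one row; `multi_ptm` marks rows
  of peptides that contributed more than one. De-duplicating by record
  id must (and, property-tested, does) restore the original peptide
  count, so PTM expansion can never inflate match statistics.

## Degeneracy-aware matching

Mass spectrometry cannot distinguish isoleucine from leucine, and
database sequences may carry the IUPAC ambiguity codes B (Asn/Asp),
Z (Glu/Gln) and X (any residue). Exact string matching would therefore
silently drop valid placements. Instead each residue is expanded to the
class of residues it is compatible with:

| residue | class |
|---|---|
| N | N, B, X |
| D | D, B, X |
| E | E, Z, X |
| Q | Q, Z, X |
| I, L | I, L, X |
| B | B, N, D, X |
| Z | Z, E, Q, X |
| X | everything |
| any other r | r, X |

so `expandDegenerate("NDEQIL")` renders
`[NBX][DBX][EZX][QZX][ILX][ILX]`. The table is symmetric by
construction (a matches b iff b matches a), which the test suite
verifies over all 25 × 25 residue pairs. The classes for targets
containing B/Z/X and for unambiguous residues ({r, X}) follow from
requiring that symmetry: B must accept exactly the residues whose
classes contain B. U (Sec) and O (Pyl) match only themselves and X —
no mass-spectrometric ambiguity class applies to them. A peptide
matches a target window when every position's residues are compatible;
all (overlapping, repeated) sites on all targets are reported, because
discarding multiplicity here would destroy information the
quantification step may need. Records with no site anywhere are
returned in an unmatched summary rather than dropped silently.

Matching is implemented as a vectorized sweep of a 25 × 25 logical
compatibility matrix over all window offsets, and is checked against an
independently written brute-force class-membership matcher on random
inputs (the test suite and the acceptance script both run this
comparison; the acceptance script uses 1,000 random pairs with targets
up to 200 residues).

Coordinates are 1-based inclusive throughout, matching how protein
domain boundaries are conventionally published; containers such as
`IRanges` share that convention, and converters to 0-based half-open
belong at I/O edges only. When peptide condition fields and target
metadata share keys, `join_on` restricts which peptide/target pairs are
scanned; the default is the full cartesian product, which is the least
surprising behavior but is documented loudly because it can multiply
matches across homologous targets.

## Per-residue quantification

For a grouping key g (e.g. donor × antibody), target t and position p:

* **PSM mode (default):** value(g, t, p) = Σ over match occurrences
  covering p of the record's PSM count, defaulting to 1 when the source
  had no PSM column. This makes the positional sum exactly
  Σ (peptide length × weight) over occurrences — an invariant the tests
  and the acceptance script verify. The phrase "number of peptides
  spanning a position" is ambiguous between occurrences and distinct
  sequences; both are offered (`count_mode = "weighted"` /
  `"distinct"`), with the weighted count as default since heatmaps are
  conventionally colored by PSM evidence.
* **Intensity / area mode:** within each group, records are first
  reduced to unique stripped sequences — duplicates aggregated by sum,
  charge deliberately ignored in the uniqueness key — then value(g, t,
  p) = Σ of aggregated quantities of unique peptides with a match
  covering p. Every per-position value is therefore bounded by the
  group's total aggregated quantity (property-tested).
* A peptide matching several sites contributes at every site, with no
  down-weighting: repeated epitopes stay visible. This choice is
  documented here precisely because the alternative (splitting weight
  across sites) is defensible; it simply answers a different question.
* Positions covered by no peptide are absent from the long table and
  render as blank/zero downstream; `coverageSummary` reports covered
  residue counts and fractions per group, including explicit zero rows
  for expected-but-empty groups when asked.

## Rendering conventions

Tiles are centered on integer residue positions with unit width, so
tile *i* spans *i* − 0.5 … *i* + 0.5 and every region boundary falls on
a half-integer edge — the alignment between heatmap, separators and
tick marks is exact in data coordinates, and the tests query those
coordinates from the figure object rather than from pixels. Defaults:
greyscale (white → black) for PSM counts, white → blue for
intensity/area, both overridable; global color normalization across
facets (cross-condition comparison is the headline use), per-facet by
option; PTM ticks in a fixed-height band above each heatmap bar, with
coincident ticks stacked in label-sorted order; CDR/mutation regions
overlaid in their configured (or category-default) colors while domain
regions get separators and labels. The legend gradient is drawn in
vector form rather than as an embedded bitmap, which keeps repeated SVG
renders byte-identical. A sidecar TSV of the exact plotted matrix is
always written next to the image; `renderComparison` stacks one panel
per metric with a shared x axis; `renderPeptideLanes` offers the
non-collapsed view with greedy first-fit lane packing. The tick-band
height and lane packing are display conventions of this package, not
measurements.

## The fixture generator

`generateTarget` draws a uniform random sequence over the 20 standard
residues, optionally replaces a stated fraction of positions with
B/Z/X, and plants disjoint labelled regions (one per equal-width
block). `generateFixture` samples peptides of length 8–15 as true
substrings of the target — typical MHC-II ligand lengths — decorates
them with 1–2 modifications from a small catalog of common PTMs
(phosphorylation, oxidation, acetylation, carbamidomethylation,
deamidation) at the requested rate, draws PSM counts of 1–5, log-10
intensities in 4–8 and areas in 3–7 (rounded to integers so every
dialect round-trips exactly), and serializes via the same dialect
registry the readers use, plus a JSON ground-truth sidecar. One integer
seed drives a single stream; identical seeds give byte-identical files.

What the generator deliberately does **not** emulate: retention times,
spectra, charge-dependent intensity structure, missed cleavages,
realistic intensity distributions, decoys or FDR structure, or
engine-specific score columns beyond placeholders. Passing tests
therefore demonstrate that parsing, stripping, mapping, roll-up and
rendering are mutually consistent and match independent oracles — not
that any engine's real-world quirks beyond the documented schemas are
handled. Real exports with renamed columns are expected and handled via
`dialect_overrides`.

## Problem sizes and numerical choices

The shipped test-suite and acceptance-script scales are the package's
own verification settings: 1,000 random peptide/target pairs (targets
≤ 200 residues, full 25-letter alphabet) for matcher/oracle agreement;
200 random fixture projects for PSM conservation; 8 planted peptides
per format for full-loop recovery; fixtures of 5–15 peptides on
120-residue targets elsewhere. Ties and degenerate inputs: empty
peptides produce empty patterns; peptides longer than the target
produce no matches; equal-value tiles get equal colors; duplicate PTM
table keys are an error rather than a silent first-wins; region
intervals are validated against their target's length at construction.

## Limitations

* No FDR filtering, score thresholding or protein inference — inputs
  are assumed to be post-QC summarized results.
* Single-residue degeneracy only; resolving longer mass-coincidence
  ambiguities (e.g. reshuffled antibody CDR assemblies) belongs to
  specialized upstream tools.
* No alignment or mismatch tolerance: a peptide either class-matches a
  window or it does not.
* Quantification does no cross-run normalization or imputation, and no
  statistical testing between conditions; the long-format TSV export is
  the intended hand-off to statistics tools.
* Automatic peptide-cluster calling on coverage maps is out of scope;
  the heatmaps are the substrate on which such judgments are made.
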