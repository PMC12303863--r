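Package: PepCoverage
Title: Peptide-to-Protein Mapping, Per-Residue Quantification and
    Coverage Heatmaps for Mass Spectrometry Search Results
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ingests peptide-level identifications from heterogeneous
    mass-spectrometry search engines (PEAKS, Spectronaut, MSFragger,
    Comet, DIA-NN, Skyline, MaxQuant) and the standardized mzTab and
    mzIdentML formats into one canonical table, strips modification
    notation, expands post-translational modifications into positional
    records, maps stripped peptides onto target protein sequences with
    degeneracy-aware residue-class matching (B/Z/X codes, I/L
    equivalence), rolls matched peptides up to per-residue PSM,
    intensity or peak-area values, and renders linearized,
    domain-annotated, multi-condition peptide coverage heatmaps with
    PTM tick marks. Includes a deterministic synthetic-fixture
    generator covering every supported input dialect and a
    command-line interface for scripted pipelines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    IRanges,
    Biostrings,
    data.table,
    ggplot2,
    patchwork,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PepCoverage-package.R'
    'cli.R'
    'dialects.R'
    'fixtures.R'
    'mapping.R'
    'plot.R'
    'quantify.R'
    'readers.R'
    'sequence.R'
    'targets.R'
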