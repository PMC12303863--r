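## Independent oracles, written directly from the stated matching rules
## and kept free of the package's internals.

ORACLE_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                     "B", "Z", "X", "U", "O")

## Residue -> set of residues it matches (hand-written rule table).
oracleClasses <- local({
  cl <- lapply(ORACLE_ALPHABET, function(r) c(r, "X"))
  names(cl) <- ORACLE_ALPHABET
  cl$N <- c("N", "B", "X"); cl$D <- c("D", "B", "X")
  cl$E <- c("E", "Z", "X"); cl$Q <- c("Q", "Z", "X")
  cl$I <- c("I", "L", "X"); cl$L <- c("I", "L", "X")
  cl$B <- c("B", "N", "D", "X"); cl$Z <- c("Z", "E", "Q", "X")
  cl$X <- ORACLE_ALPHABET
  cl
})

## All 1-based start offsets where the peptide matches the target:
## plain double loop testing class membership at every offset.
oracleMatchStarts <- function(peptide, target) {
  p <- strsplit(peptide, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(p); L <- length(t)
  if (n == 0 || L < n) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(L - n + 1)) {
    ok <- TRUE
    for (j in seq_len(n)) {
      if (!(t[s + j - 1] %in% oracleClasses[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

## Brute-force per-position PSM accumulation over match occurrences.
brutePsmByPosition <- function(starts, ends, weights) {
  acc <- numeric(0)
  for (i in seq_along(starts)) {
    for (p in starts[i]:ends[i]) {
      key <- as.character(p)
      acc[key] <- (if (key %in% names(acc)) acc[[key]] else 0) + weights[i]
    }
  }
  acc
}

randomPeptide <- function(len, alphabet = ORACLE_ALPHABET) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## Pipeline shorthand used by many tests.
readAndStrip <- function(path, platform, labels = NULL) {
  processSequences(readResults(path, platform, labels))
}
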