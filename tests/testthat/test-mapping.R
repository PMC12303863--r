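test_that("degeneracy expansion renders the canonical class pattern", {
  expect_identical(as.character(expandDegenerate("NDEQIL")),
                   "[NBX][DBX][EZX][QZX][ILX][ILX]")
  expect_identical(as.character(expandDegenerate("")), "")
  expect_identical(as.character(expandDegenerate("AG")), "[AX][GX]")
  expect_identical(as.character(expandDegenerate("BZX")),
                   paste0("[BNDX][ZEQX][X", paste(setdiff(ORACLE_ALPHABET,
                                                          "X"),
                                                  collapse = ""), "]"))
  err <- expect_error(expandDegenerate("AJG"), "outside residue alphabet")
  expect_match(conditionMessage(err), "'J' at offset 2")
})

test_that("the residue compatibility relation is symmetric over all pairs", {
  M <- PepCoverage:::residueCompatMatrix()
  for (a in ORACLE_ALPHABET) for (b in ORACLE_ALPHABET) {
    expect_identical(M[a, b], M[b, a])
    expect_identical(M[a, b], b %in% oracleClasses[[a]])
  }
})

test_that("matching reports coordinates, interchangeable residues and degenerate codes", {
  tgt <- targetSet(c(T1 = "AANDEQILGG"))
  ms <- matchPeptides(peptideSet(data.frame(stripped_sequence = "NDEQIL")),
                      tgt)
  m <- as.data.frame(matches(ms))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(3L, 8L))

  ms2 <- matchPeptides(peptideSet(data.frame(stripped_sequence = "IL")),
                       targetSet(c(T1 = "LI")))
  m2 <- as.data.frame(matches(ms2))
  expect_equal(c(m2$start, m2$end), c(1L, 2L))

  ms3 <- matchPeptides(peptideSet(data.frame(stripped_sequence = "AAA")),
                       targetSet(c(T1 = "GGG")))
  expect_equal(nrow(matches(ms3)), 0L)
  expect_equal(nrow(unmatchedRecords(ms3)), 1L)

  ms4 <- matchPeptides(peptideSet(data.frame(stripped_sequence = "NN")),
                       targetSet(c(T1 = "BN")))
  m4 <- as.data.frame(matches(ms4))
  expect_equal(m4$start, 1L)
})

test_that("overlapping and repeated match sites are all reported", {
  ms <- matchPeptides(peptideSet(data.frame(stripped_sequence = "AA")),
                      targetSet(c(T1 = "AAAA")))
  expect_equal(as.data.frame(matches(ms))$start, 1:3)
})

test_that("matching agrees exactly with the brute-force class oracle", {
  set.seed(501)
  for (rep in 1:60) {
    pep <- randomPeptide(sample(5:15, 1))
    tgt <- randomPeptide(sample(20:200, 1))
    got <- matchPeptides(peptideSet(data.frame(stripped_sequence = pep)),
                         targetSet(c(T1 = tgt)))
    expect_identical(as.data.frame(matches(got))$start,
                     oracleMatchStarts(pep, tgt),
                     info = paste(pep, substr(tgt, 1, 30)))
  }
})

test_that("every match window has the peptide's length and X-substitution never loses matches", {
  set.seed(502)
  for (rep in 1:20) {
    pep <- randomPeptide(sample(5:10, 1))
    tgt <- randomPeptide(100)
    ms <- matchPeptides(peptideSet(data.frame(stripped_sequence = pep)),
                        targetSet(c(T1 = tgt)))
    m <- as.data.frame(matches(ms))
    if (nrow(m))
      expect_true(all(m$end - m$start + 1L == nchar(pep)))
    at <- sample(nchar(pep), 1)
    pep_x <- pep
    substr(pep_x, at, at) <- "X"
    mx <- matchPeptides(peptideSet(data.frame(stripped_sequence = pep_x)),
                        targetSet(c(T1 = tgt)))
    expect_true(all(m$start %in% as.data.frame(matches(mx))$start))
  }
})

test_that("condition/metadata joins restrict which targets are scanned", {
  ps <- peptideSet(data.frame(stripped_sequence = c("PEPT", "PEPT"),
                              antibody = c("mAb1", "mAb2")))
  tgt <- targetSet(c(A = "GGPEPTGG", B = "PEPTAAAA"),
                   meta = data.frame(target_id = c("A", "B"),
                                     antibody = c("mAb1", "mAb2")))
  m <- as.data.frame(matches(matchPeptides(ps, tgt, join_on = "antibody")))
  expect_equal(m$target_id[m$record_id == "r1"], "A")
  expect_equal(m$target_id[m$record_id == "r2"], "B")
  ## cartesian default scans everything
  m2 <- as.data.frame(matches(matchPeptides(ps, tgt)))
  expect_equal(nrow(m2), 4L)
  expect_error(matchPeptides(ps, tgt, join_on = "donor"), "join_on")
})

test_that("region labels attach on inclusive interval overlap, ordered by start", {
  tgt <- targetSet(c(T1 = paste(rep("A", 12), collapse = "")),
                   regions = data.frame(
                     target_id = "T1",
                     label = c("R_late", "R_early"),
                     start = c(8L, 1L), end = c(10L, 3L),
                     category = "domain"))
  ps <- peptideSet(data.frame(stripped_sequence = "AAAAAA"))
  ms <- annotateRegions(matchPeptides(ps, tgt), tgt)
  m <- as.data.frame(matches(ms))
  lab38 <- matches(ms)$region_labels[[which(m$start == 3)]]
  expect_equal(lab38, c("R_early", "R_late"))
  lab48 <- matches(ms)$region_labels[[which(m$start == 4)]]
  expect_equal(lab48, "R_late")
  ## no overlap: interval ends just before the region
  tgt2 <- targetSet(c(T1 = paste(rep("A", 12), collapse = "")),
                    regions = data.frame(target_id = "T1", label = "R",
                                         start = 9L, end = 12L,
                                         category = "domain"))
  ms2 <- annotateRegions(matchPeptides(
    peptideSet(data.frame(stripped_sequence = "AAAAAA")), tgt2), tgt2)
  m2 <- as.data.frame(matches(ms2))
  expect_equal(lengths(matches(ms2)$region_labels[m2$start == 1]), 0L)
  expect_equal(lengths(matches(ms2)$region_labels[m2$start == 4]), 1L)
})

test_that("region validity is enforced against the referenced target", {
  expect_error(targetSet(c(T1 = "AAAA"),
                         regions = data.frame(target_id = "T1",
                                              label = "R", start = 2L,
                                              end = 9L,
                                              category = "domain")),
               "outside")
  expect_error(targetSet(c(T1 = "AAAA"),
                         regions = data.frame(target_id = "T9",
                                              label = "R", start = 1L,
                                              end = 2L,
                                              category = "domain")),
               "unknown target_id")
})

test_that("targets read from FASTA and TSV are equivalent", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "t.fasta")
  writeLines(c(">HC chain=HC", "AANDEQILGG", ">LC chain=LC", "PEPTIDEK"),
             fa)
  tsv <- file.path(d, "t.tsv")
  writeLines(c("target_id\tchain\tsequence", "HC\tHC\tAANDEQILGG",
               "LC\tLC\tPEPTIDEK"), tsv)
  t1 <- readTargets(fa)
  t2 <- readTargets(tsv)
  expect_equal(as.character(targetSequences(t1)),
               as.character(targetSequences(t2)))
  expect_equal(targetMeta(t1)$chain, c("HC", "LC"))
})
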