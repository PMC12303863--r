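quantOf <- function(pq) as.data.frame(quantTable(pq))

test_that("a single unweighted peptide contributes one PSM at each covered residue", {
  tgt <- targetSet(c(T1 = "AANDEQILGG"))
  ps <- peptideSet(data.frame(stripped_sequence = "NDEQIL"))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps)
  q <- quantOf(pq)
  expect_equal(q$position, 3:8)
  expect_equal(q$value, rep(1, 6))
  expect_equal(sum(q$value), 6)
})

test_that("overlapping weighted peptides accumulate per position", {
  tgt <- targetSet(c(T1 = "ABCDEFGH"))
  ps <- peptideSet(data.frame(stripped_sequence = c("ABCD", "CDEF"),
                              psm = c(2, 1)))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps)
  q <- quantOf(pq)
  expect_equal(q$value[match(1:6, q$position)], c(2, 2, 3, 3, 1, 1))
})

test_that("intensity mode aggregates duplicate sequences before roll-up", {
  tgt <- targetSet(c(T1 = "APEPSGG"))
  ps <- peptideSet(data.frame(stripped_sequence = c("PEPS", "PEPS"),
                              intensity = c(100, 50)))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps,
                          metric = "intensity")
  q <- quantOf(pq)
  expect_equal(q$position, 2:5)
  expect_equal(q$value, rep(150, 4))
})

test_that("psm-mode positional sums are conserved", {
  set.seed(601)
  for (rep in 1:10) {
    tgt <- generateTarget(60, seed = 600 + rep)
    tseq <- as.character(targetSequences(tgt))[[1]]
    n <- sample(3:8, 1)
    st <- sample(50, n, replace = TRUE)
    len <- sample(5:10, n, replace = TRUE)
    ps <- peptideSet(data.frame(
      stripped_sequence = substring(tseq, st, pmin(st + len - 1, 60)),
      psm = sample(1:4, n, replace = TRUE)))
    ms <- matchPeptides(ps, tgt)
    pq <- quantifyPositions(ms, ps)
    m <- merge(as.data.frame(matches(ms)), as.data.frame(records(ps)),
               by = "record_id")
    expect_equal(sum(quantOf(pq)$value),
                 sum((m$end - m$start + 1) * m$psm))
  }
})

test_that("per-position roll-up equals the brute-force oracle", {
  set.seed(602)
  for (rep in 1:15) {
    tgt <- generateTarget(100, seed = 650 + rep)
    tseq <- as.character(targetSequences(tgt))[[1]]
    n <- sample(5:20, 1)
    st <- sample(90, n, replace = TRUE)
    ps <- peptideSet(data.frame(
      stripped_sequence = substring(tseq, st, pmin(st + sample(5:12, n,
        replace = TRUE) - 1, 100)),
      psm = sample(1:5, n, replace = TRUE)))
    ms <- matchPeptides(ps, tgt)
    pq <- quantifyPositions(ms, ps)
    m <- merge(as.data.frame(matches(ms)), as.data.frame(records(ps)),
               by = "record_id")
    oracle <- brutePsmByPosition(m$start, m$end, m$psm)
    q <- quantOf(pq)
    expect_equal(setNames(q$value, q$position),
                 oracle[order(as.integer(names(oracle)))])
  }
})

test_that("per-position intensity never exceeds the group's aggregated total", {
  set.seed(603)
  tgt <- generateTarget(80, seed = 660)
  tseq <- as.character(targetSequences(tgt))[[1]]
  st <- sample(70, 12, replace = TRUE)
  ps <- peptideSet(data.frame(
    stripped_sequence = substring(tseq, st, pmin(st + 7, 80)),
    intensity = round(10^runif(12, 3, 6))))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps,
                          metric = "intensity")
  rec <- as.data.frame(records(ps))
  total <- sum(tapply(rec$intensity, rec$stripped_sequence, sum))
  expect_true(all(quantOf(pq)$value <= total + 1e-9))
})

test_that("group-wise quantification is additive over disjoint groups", {
  d <- withr::local_tempdir()
  fx <- generateFixture("maxquant", 8, mod_rate = 0, seed = 73, dir = d)
  ps <- readAndStrip(fx$path, "maxquant", list(list(donor = "D1")))
  d2 <- withr::local_tempdir()
  fx2 <- generateFixture("maxquant", 8, mod_rate = 0, seed = 74, dir = d2,
                         target = fx$target)
  both <- readAndStrip(c(fx$path, fx2$path), "maxquant",
                       list(list(donor = "D1"), list(donor = "D2")))
  ms <- matchPeptides(both, fx$target)
  pq <- quantifyPositions(ms, both, group_by = "donor")
  q <- quantOf(pq)
  for (dn in c("D1", "D2")) {
    keep <- as.data.frame(records(both))$donor == dn
    sub <- new("PeptideSet", records = records(both)[keep, ],
               conditionFields = conditionFields(both))
    pq_one <- quantifyPositions(matchPeptides(sub, fx$target), sub)
    qo <- quantOf(pq_one)
    qg <- q[q$donor == dn, ]
    expect_equal(setNames(qg$value, qg$position),
                 setNames(qo$value, qo$position), info = dn)
  }
})

test_that("distinct-peptide counting ignores PSM weights and duplicates", {
  tgt <- targetSet(c(T1 = "ABCDEFGH"))
  ps <- peptideSet(data.frame(stripped_sequence = c("ABCD", "ABCD", "CDEF"),
                              psm = c(5, 2, 7)))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps,
                          count_mode = "distinct")
  q <- quantOf(pq)
  expect_equal(q$value[match(1:6, q$position)], c(1, 1, 2, 2, 1, 1))
})

test_that("requesting an absent metric or a bad group is a configuration error", {
  tgt <- targetSet(c(T1 = "ABCDEFGH"))
  ps <- peptideSet(data.frame(stripped_sequence = "ABCD"))
  ms <- matchPeptides(ps, tgt)
  expect_error(quantifyPositions(ms, ps, metric = "intensity"),
               "absent")
  expect_error(quantifyPositions(ms, ps, group_by = "donor"),
               "donor")
})

test_that("records without intensity contribute zero, with a warning", {
  tgt <- targetSet(c(T1 = "ABCDEFGH"))
  ps <- peptideSet(data.frame(stripped_sequence = c("ABCD", "CDEF"),
                              intensity = c(100, NA)))
  expect_warning(
    pq <- quantifyPositions(matchPeptides(ps, tgt), ps,
                            metric = "intensity"),
    "contribute 0")
  q <- quantOf(pq)
  expect_equal(q$value[match(1:6, q$position)], c(100, 100, 100, 100, 0, 0))
})

test_that("coverage summaries report covered residues and fractions", {
  tgt <- targetSet(c(T1 = "AANDEQILGG"))
  ps <- peptideSet(data.frame(stripped_sequence = "NDEQIL"))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps)
  s <- coverageSummary(pq, tgt)
  expect_equal(s$covered, 6L)
  expect_equal(s$fraction, 0.6)
  expect_equal(s$max_value, 1)
  ## expected-but-uncovered groups appear with zero coverage
  s2 <- coverageSummary(pq, tgt,
                        groups = data.frame(target_id = c("T1", "T1"),
                                            stringsAsFactors = FALSE))
  expect_equal(nrow(coverageSummary(pq, tgt)), 1L)
  pq_empty <- quantifyPositions(
    matchPeptides(peptideSet(data.frame(stripped_sequence = "WWWW")),
                  tgt), ps)
  s3 <- coverageSummary(pq_empty, tgt,
                        groups = data.frame(target_id = "T1"))
  expect_equal(s3$covered, 0L)
  expect_equal(s3$fraction, 0)
})
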