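## A controlled scene used across rendering tests: one length-10 target,
## a single peptide covering residues 3..8, one domain region 1..5.
plotScene <- function() {
  tgt <- targetSet(c(T1 = "AANDEQILGG"),
                   regions = data.frame(target_id = "T1", label = "VH",
                                        start = 1L, end = 5L,
                                        category = "domain"))
  ps <- peptideSet(data.frame(stripped_sequence = "NDEQIL"))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps)
  list(tgt = tgt, ps = ps, pq = pq)
}

layersOfClass <- function(p, cls) {
  Filter(function(l) inherits(l$geom, cls), p$layers)
}

test_that("a controlled input renders to a decodable image with one gray level", {
  skip_if_not_installed("png")
  sc <- plotScene()
  f <- file.path(withr::local_tempdir(), "cov.png")
  out <- renderCoveragePlot(sc$pq, sc$tgt, config = plotConfig(
    domain_labels = FALSE), file = f)
  expect_true(file.exists(f))
  img <- png::readPNG(f)
  expect_gte(length(dim(img)), 3)
  ## heatmap band: gray pixels (r==g==b) that are not background white
  ## or the grey frame/separator tones
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  grayish <- abs(r - g) < 1e-6 & abs(g - b) < 1e-6 & r < 0.3
  expect_true(any(grayish))
  ## dominant dark-gray levels (ignoring antialiased edges / text strokes)
  tab <- table(round(r[grayish], 2))
  dominant <- as.numeric(names(tab)[tab / sum(tab) > 0.2])
  expect_equal(length(dominant), 1L)
  expect_lt(dominant, 0.05)  # value 1 of 1 maps to full black
  expect_true(file.exists(out$sidecar))
})

test_that("region separators sit at half-integer data coordinates", {
  sc <- plotScene()
  p <- renderCoveragePlot(sc$pq, sc$tgt, config = plotConfig())$plot
  vl <- layersOfClass(p, "GeomVline")
  expect_length(vl, 1)
  xs <- sort(ggplot2::layer_data(p, which(vapply(
    p$layers, function(l) inherits(l$geom, "GeomVline"),
    logical(1))))$xintercept)
  expect_equal(xs, c(0.5, 5.5))
  expect_true(all(abs(xs %% 1 - 0.5) < 1e-9))
})

test_that("PTM tick marks land on their residue's x coordinate", {
  sc <- plotScene()
  ticks <- data.frame(target_id = "T1", position = 4L,
                      ptm_label = "Phospho (STY)")
  p <- renderCoveragePlot(sc$pq, sc$tgt, ptm_positions = ticks,
                          config = plotConfig())$plot
  seg_i <- which(vapply(p$layers, function(l)
    inherits(l$geom, "GeomSegment"), logical(1)))
  expect_length(seg_i, 1)
  ld <- ggplot2::layer_data(p, seg_i)
  expect_equal(ld$x, 4)
  expect_equal(ld$xend, 4)
  expect_gt(min(ld$y), 1)  # tick band sits above the heatmap bar
})

test_that("coincident ticks stack vertically in label order", {
  sc <- plotScene()
  ticks <- data.frame(target_id = "T1", position = c(4L, 4L),
                      ptm_label = c("B-mod", "A-mod"))
  p <- renderCoveragePlot(sc$pq, sc$tgt, ptm_positions = ticks,
                          config = plotConfig())$plot
  seg_i <- which(vapply(p$layers, function(l)
    inherits(l$geom, "GeomSegment"), logical(1)))
  ld <- ggplot2::layer_data(p, seg_i)
  expect_equal(nrow(ld), 2)
  expect_equal(length(unique(ld$y)), 2)
})

test_that("normalization mode is immaterial when groups carry identical data", {
  tgt <- targetSet(c(T1 = "AANDEQILGG"))
  ps <- peptideSet(data.frame(stripped_sequence = c("NDEQIL", "NDEQIL"),
                              donor = c("D1", "D2")))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps, group_by = "donor")
  fills <- lapply(c("global", "per_facet"), function(norm) {
    p <- renderCoveragePlot(pq, tgt, config = plotConfig(
      scale_normalization = norm))$plot
    tile_i <- which(vapply(p$layers, function(l)
      inherits(l$geom, "GeomTile"), logical(1)))
    ggplot2::layer_data(p, tile_i)$fill
  })
  expect_identical(fills[[1]], fills[[2]])
})

test_that("greyscale tiles darken monotonically with value", {
  tgt <- targetSet(c(T1 = "GGABCDGGGG"))
  ps <- peptideSet(data.frame(stripped_sequence = c("ABCD", "ABC", "AB"),
                              psm = c(1, 1, 1)))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps)
  p <- renderCoveragePlot(pq, tgt, config = plotConfig())$plot
  tile_i <- which(vapply(p$layers, function(l)
    inherits(l$geom, "GeomTile"), logical(1)))
  ld <- ggplot2::layer_data(p, tile_i)
  lum <- apply(grDevices::col2rgb(ld$fill), 2, mean)
  q <- as.data.frame(quantTable(pq))
  vals <- q$value[match(round(ld$x), q$position)]
  ## higher value => darker or equal tile luminance
  ord <- order(vals)
  expect_true(all(diff(lum[ord]) <= 1e-9))
  expect_gt(length(unique(vals)), 2)
})

test_that("svg output is byte-identical across repeated renders", {
  sc <- plotScene()
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.svg"); f2 <- file.path(d, "b.svg")
  renderCoveragePlot(sc$pq, sc$tgt, config = plotConfig(), file = f1)
  renderCoveragePlot(sc$pq, sc$tgt, config = plotConfig(), file = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empty quant errors unless explicitly allowed", {
  tgt <- targetSet(c(T1 = "AANDEQILGG"))
  ps <- peptideSet(data.frame(stripped_sequence = "WWWW"))
  pq <- quantifyPositions(matchPeptides(ps, tgt), ps)
  expect_error(renderCoveragePlot(pq, tgt), "empty quant")
  out <- renderCoveragePlot(pq, tgt,
                            config = plotConfig(allow_empty = TRUE))
  expect_s3_class(out$plot, "ggplot")
})

test_that("strict color mode rejects unconfigured region labels", {
  sc <- plotScene()
  expect_error(
    renderCoveragePlot(sc$pq, sc$tgt,
                       config = plotConfig(strict_colors = TRUE)),
    "no color configured")
  ok <- renderCoveragePlot(sc$pq, sc$tgt, config = plotConfig(
    strict_colors = TRUE, region_colors = c(VH = "#AABBCC")))
  expect_s3_class(ok$plot, "ggplot")
})

test_that("stacked metric panels share the x extent and count", {
  d <- withr::local_tempdir()
  fx <- generateFixture("maxquant", 8, mod_rate = 0.3, seed = 77, dir = d)
  ps <- readAndStrip(fx$path, "maxquant")
  ms <- matchPeptides(ps, fx$target)
  pqs <- list(quantifyPositions(ms, ps, metric = "psm"),
              quantifyPositions(ms, ps, metric = "intensity"),
              quantifyPositions(ms, ps, metric = "area"))
  out <- renderComparison(pqs, fx$target, config = plotConfig())
  expect_length(out$panels, 3)
  xranges <- lapply(out$panels, function(p)
    ggplot2::ggplot_build(p)$layout$panel_params[[1]]$x.range)
  expect_equal(xranges[[1]], xranges[[2]])
  expect_equal(xranges[[1]], xranges[[3]])
  ## single panel degenerates to the plain coverage plot
  one <- renderComparison(pqs[1], fx$target, config = plotConfig())
  expect_s3_class(one$plot, "ggplot")
  ## mismatched targets across panels are rejected
  tgt2 <- targetSet(c(OTHER = "AANDEQILGG"))
  ps2 <- peptideSet(data.frame(stripped_sequence = "NDEQIL"))
  pq2 <- quantifyPositions(matchPeptides(ps2, tgt2), ps2)
  expect_error(renderComparison(list(pqs[[1]], pq2), fx$target),
               "different targets")
})

test_that("the sidecar matrix reproduces the plotted values", {
  sc <- plotScene()
  f <- file.path(withr::local_tempdir(), "cov.pdf")
  out <- renderCoveragePlot(sc$pq, sc$tgt, config = plotConfig(),
                            file = f)
  side <- data.table::fread(out$sidecar, header = TRUE)
  expect_equal(colnames(side), c("target_id", "group", as.character(3:8)))
  expect_equal(unname(unlist(side[1, as.character(3:8), with = FALSE])),
               rep(1, 6))
})

test_that("per-peptide lanes pack occurrences without overlap", {
  tgt <- targetSet(c(T1 = "AAAAAAAAAA"))
  ps <- peptideSet(data.frame(stripped_sequence = c("AAAA", "AAAA")))
  ms <- matchPeptides(ps, tgt)
  out <- renderPeptideLanes(ms, tgt)
  ld <- out$plot$data
  for (lane in unique(ld$lane)) {
    seg <- ld[ld$lane == lane, ]
    seg <- seg[order(seg$start), ]
    if (nrow(seg) > 1)
      expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
  }
})
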