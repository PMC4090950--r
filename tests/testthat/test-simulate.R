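test_that("generators are pure functions of the config", {
  cfg <- syntheticConfig(seed = 71, nChroms = 1L, chromLength = 1e6,
                         nEnhancers = 20L, nRepeats = 500L, nGenes = 40L)
  a1 <- generateAnnotations(cfg)
  a2 <- generateAnnotations(cfg)
  expect_identical(start(a1$repeats), start(a2$repeats))
  expect_identical(start(anchors(a1$enhancers)),
                   start(anchors(a2$enhancers)))
  expect_identical(start(a1$genes), start(a2$genes))

  cls <- classifyRepeats(a1$enhancers, a1$repeats)
  s1 <- generateSequences(cfg, a1$repeats, mcols(cls)$label)
  s2 <- generateSequences(cfg, a2$repeats, mcols(cls)$label)
  expect_identical(as.character(s1), as.character(s2))

  t1 <- generateTracks(cfg, a1$enhancers, a1$layout)
  t2 <- generateTracks(cfg, a2$enhancers, a2$layout)
  expect_identical(start(tagPositions(t1$H3K4me1)),
                   start(tagPositions(t2$H3K4me1)))

  d <- rep(0, 40)
  expect_identical(generateExpression(cfg, a1$genes, d),
                   generateExpression(cfg, a2$genes, d))
})

test_that("annotation geometry respects spacing and packing limits", {
  cfg <- syntheticConfig(seed = 72, nChroms = 2L, chromLength = 2e6,
                         nEnhancers = 100L, nRepeats = 1000L, nGenes = 100L)
  ann <- generateAnnotations(cfg)
  a <- anchors(ann$enhancers)
  for (ch in GenomeInfoDb::seqlevels(a)) {
    pos <- sort(start(a[GenomeInfoDb::seqnames(a) == ch]))
    if (length(pos) > 1) expect_true(all(diff(pos) >= 8000L))
  }
  expect_length(findOverlaps(ann$genes, drop.self = TRUE,
                             drop.redundant = TRUE), 0L)
  expect_error(
    generateAnnotations(syntheticConfig(seed = 1, nChroms = 1L,
                                        chromLength = 100000L,
                                        nEnhancers = 50L)),
    "infeasible")
})

test_that("repeat placement recovers the configured fold", {
  # null construction: fold 1 means uniform density
  cfg1 <- syntheticConfig(seed = 73, enhancerRepeatFold = 1,
                          nRepeats = 50000L)
  ann1 <- generateAnnotations(cfg1)
  spans1 <- suppressMessages(enhancerSpans(ann1$enhancers))
  fold1 <- featureDensityFold(spans1, ann1$repeats, ann1$layout)
  expect_lt(abs(fold1 - 1), 0.05)

  cfg3 <- syntheticConfig(seed = 74, enhancerRepeatFold = 3,
                          nRepeats = 50000L)
  ann3 <- generateAnnotations(cfg3)
  spans3 <- suppressMessages(enhancerSpans(ann3$enhancers))
  fold3 <- featureDensityFold(spans3, ann3$repeats, ann3$layout)
  expect_lt(abs(fold3 - 3) / 3, 0.1)
})

test_that("active tracks show the calibrated central bump and the repressive mark dips", {
  cfg <- syntheticConfig(seed = 75)
  ann <- generateAnnotations(cfg)
  tracks <- generateTracks(cfg, ann$enhancers, ann$layout)
  a <- anchors(ann$enhancers)

  profAct <- suppressMessages(metaprofile(a, tracks$H3K4me1))
  central <- foldEnrichment(profAct)[20]
  # ~200 features x ~25 tags in the central window: se ~ 1.4% of 5
  expect_lt(abs(central - 5), 0.3)
  # bump decays symmetrically: flanking windows lower than center
  expect_gt(central, foldEnrichment(profAct)[16])
  expect_gt(central, foldEnrichment(profAct)[24])
  edge <- foldEnrichment(profAct)[c(1:4, 37:40)]
  expect_true(all(abs(edge - 1) < 0.2))

  profRep <- suppressMessages(metaprofile(a, tracks$H3K27me3))
  expect_lt(abs(foldEnrichment(profRep)[20] - 0.2), 0.06)

  # bump height 1: flat track
  cfg0 <- syntheticConfig(seed = 76, bumpHeight = 1)
  tr0 <- generateTracks(cfg0, ann$enhancers, ann$layout,
                        marks = c(flat = "active"))
  prof0 <- suppressMessages(metaprofile(a, tr0$flat))
  expect_true(all(abs(foldEnrichment(prof0) - 1) < 0.2))
})

test_that("planted motif rates separate targets from background", {
  cfg <- syntheticConfig(seed = 77)
  ann <- generateAnnotations(cfg)
  cls <- classifyRepeats(ann$enhancers, ann$repeats)
  lab <- mcols(cls)$label
  seqs <- generateSequences(cfg, ann$repeats, lab)
  isTarget <- lab %in% c("MIR_ENHANCER", "ENHANCER_MIR")
  motif <- RegexMotif("planted", cfg$motif)
  rateT <- countMotifHits(seqs[isTarget], motif) / sum(isTarget)
  rateB <- countMotifHits(seqs[!isTarget], motif) / sum(!isTarget)
  expect_gt(rateT, rateB + 0.2)

  # equal rates: empirical test is null-centered
  cfgEq <- syntheticConfig(seed = 78, motifPlantRateTarget = 0.05)
  seqsEq <- generateSequences(cfgEq, ann$repeats, lab)
  idx <- which(isTarget & width(seqsEq) <= 250)[1:100]
  res <- empiricalMotifTest(seqsEq[idx],
                            seqsEq[!isTarget & width(seqsEq) >= 250],
                            motif, nReps = 100, seed = 3)
  expect_lt(abs(zScore(res)), 3)

  # power: planted rate 0.5 vs 0.05 gives Z > 3 at 200 targets
  zs <- vapply(1:5, function(s) {
    cfgS <- syntheticConfig(seed = 80 + s)
    seqsS <- generateSequences(cfgS, ann$repeats, lab)
    idxT <- which(isTarget & width(seqsS) <= 250)[1:200]
    zScore(empiricalMotifTest(seqsS[idxT],
                              seqsS[!isTarget & width(seqsS) >= 250],
                              motif, nReps = 100, seed = s))
  }, numeric(1))
  expect_true(all(zs > 3))
})

test_that("sequences shorter than the motif skip planting with a warning", {
  cfg <- syntheticConfig(seed = 79, motifPlantRateTarget = 1,
                         motifPlantRateBackground = 1)
  reps <- granges0("chr1", c(0, 100), c(4, 400))  # one 4 bp repeat
  names(reps) <- c("tiny", "ok")
  expect_warning(
    seqs <- generateSequences(cfg, reps, c("ENHANCER_MIR", "ENHANCER_MIR")),
    "skipped")
  expect_equal(unname(width(seqs)), c(4L, 300L))
})

test_that("writeSyntheticData produces a readable plain-text dataset", {
  dir <- withr::local_tempdir()
  cfg <- syntheticConfig(seed = 81, nChroms = 1L, chromLength = 500000L,
                         nEnhancers = 10L, nRepeats = 200L, nGenes = 15L)
  paths <- suppressMessages(writeSyntheticData(cfg, dir))
  layout <- readChromSizes(paths$sizes)
  expect_equal(unname(GenomeInfoDb::seqlengths(layout)), 500000L)
  enh <- readEnhancerAnchors(paths$enhancers, layout)
  expect_equal(length(enh), 10L)
  reps <- readBed(paths$repeats, layout)
  expect_length(reps, 200L)
  expr <- readExpressionMatrix(paths$expression)
  expect_equal(dim(expr), c(15L, 6L))
  seqs <- Biostrings::readDNAStringSet(paths$sequences)
  expect_length(seqs, 200L)
  track <- readSignalTrack(paths$track_H3K4me1, layout, format = "bed")
  expect_gt(tagCount(track), 0)

  # identical seed, identical bytes
  dir2 <- withr::local_tempdir()
  suppressMessages(writeSyntheticData(cfg, dir2))
  expect_identical(readLines(file.path(dir, "repeats.bed")),
                   readLines(file.path(dir2, "repeats.bed")))
})
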