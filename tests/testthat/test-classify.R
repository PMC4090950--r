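mkEnh <- function(pos0, layout = NULL, ...) EnhancerSet("chr1", pos0 = pos0,
                                                        layout = layout, ...)

test_that("classifyRepeats applies the anchor / span / neither rule", {
  enh <- mkEnh(5000)
  reps <- granges0(rep("chr1", 3), c(4900, 8500, 20000),
                   c(5100, 8700, 20200))
  names(reps) <- c("r1", "r2", "r3")
  cls <- classifyRepeats(enh, reps)
  expect_equal(as.character(mcols(cls)$label),
               c("MIR_ENHANCER", "ENHANCER_MIR", "NON_ENHANCER_MIR"))
  expect_equal(mcols(cls)$linkedEnhancers[[1]], names(anchors(enh)))
  expect_equal(mcols(cls)$linkedEnhancers[[2]], names(anchors(enh)))
  expect_length(mcols(cls)$linkedEnhancers[[3]], 0L)
})

test_that("classifyRepeats agrees with a brute-force scan and partitions the set", {
  set.seed(21)
  for (rep in 1:20) {
    nE <- sample(1:6, 1); nR <- sample(1:40, 1)
    anchors0 <- sort(sample(seq(5000, 195000, by = 1), nE))
    enh <- mkEnh(anchors0)
    rs <- sample(0:200000, nR, replace = TRUE)
    reps <- granges0("chr1", rs, rs + sample(50:400, nR, TRUE))
    names(reps) <- sprintf("r%03d", seq_len(nR))
    cls <- classifyRepeats(enh, reps)
    # brute force: 0-based anchor a is in [s0, e0); span is [a-4000, a+4000)
    want <- vapply(seq_len(nR), function(i) {
      s0 <- start(reps)[i] - 1L; e0 <- end(reps)[i]
      if (any(anchors0 >= s0 & anchors0 < e0)) return("MIR_ENHANCER")
      spanOver <- any(pmax(s0, anchors0 - 4000) < pmin(e0, anchors0 + 4000))
      if (spanOver) "ENHANCER_MIR" else "NON_ENHANCER_MIR"
    }, character(1))
    expect_equal(as.character(mcols(cls)$label), want)
    expect_equal(sum(table(mcols(cls)$label)), nR)  # exhaustive partition
  }
})

test_that("anchor-on-boundary containment is half-open", {
  # repeat [1000, 1200): anchor at 0-based 1000 is inside, 1200 is not
  reps <- granges0("chr1", 1000, 1200)
  names(reps) <- "r"
  expect_equal(as.character(mcols(classifyRepeats(mkEnh(1000), reps))$label),
               "MIR_ENHANCER")
  expect_equal(as.character(mcols(classifyRepeats(mkEnh(1200), reps))$label),
               "ENHANCER_MIR")
})

test_that("expectedCoreCount is enhancer density times merged repeat length", {
  layout <- GenomeInfoDb::Seqinfo(seqnames = "chr1", seqlengths = 1000000L)
  enh <- mkEnh(seq(100000, by = 50000, length.out = 10))
  reps <- granges0("chr1", seq(0, by = 20000, length.out = 50),
                   seq(0, by = 20000, length.out = 50) + 1000L)
  expect_equal(expectedCoreCount(enh, reps, layout), 10 / 1e6 * 50000)
  expect_equal(expectedCoreCount(enh, GRanges(), layout), 0)
  # repeats tiling the whole genome -> every enhancer expected
  expect_equal(expectedCoreCount(enh, granges0("chr1", 0, 1e6), layout), 10)
  # per-repeat counting: each annotated repeat contributes its length,
  # so duplicating the annotation set doubles the expectation
  expect_equal(expectedCoreCount(enh, c(reps, reps), layout),
               2 * expectedCoreCount(enh, reps, layout))
})

test_that("expectedEnhancersWithRepeats matches the uniform-placement closed form", {
  layout <- GenomeInfoDb::Seqinfo(seqnames = "chr1", seqlengths = 100000L)
  # one span of S = 10 kb in the middle, one site of length L = 500:
  # P(overlap) = (S + L - 1) / (G - L + 1)
  enh <- EnhancerSet("chr1", pos0 = 50000, layout = layout,
                     spanHalfWidth = 5000L)
  site <- granges0("chr1", 0, 500)
  m <- expectedEnhancersWithRepeats(enh, site, layout, nReps = 2000L,
                                    seed = 31)
  p <- (10000 + 500 - 1) / (100000 - 500 + 1)
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(m - p), 4 * se)

  expect_equal(as.numeric(expectedEnhancersWithRepeats(enh, GRanges(),
                                                       layout, 10L)), 0)
  # span covering the whole genome: any site certainly overlaps
  whole <- EnhancerSet("chr1", pos0 = 50000, layout = layout,
                       spanHalfWidth = 50000L)
  expect_equal(as.numeric(expectedEnhancersWithRepeats(
    whole, site, layout, nReps = 20L, seed = 1)), 1)
  expect_error(expectedEnhancersWithRepeats(enh, granges0("chr1", 0, 1e6),
                                            layout, 10L), "longer")
})

test_that("simulated expectation standard error shrinks as 1/sqrt(nReps)", {
  layout <- GenomeInfoDb::Seqinfo(seqnames = "chr1", seqlengths = 200000L)
  enh <- EnhancerSet("chr1", pos0 = c(50000, 120000), layout = layout)
  rs <- seq(0, by = 6000, length.out = 20)
  reps <- granges0("chr1", rs, rs + 300L)
  means100 <- vapply(1:20, function(s)
    as.numeric(expectedEnhancersWithRepeats(enh, reps, layout, 100L,
                                            seed = s)), numeric(1))
  means1600 <- vapply(1:20, function(s)
    as.numeric(expectedEnhancersWithRepeats(enh, reps, layout, 1600L,
                                            seed = 1000 + s)), numeric(1))
  ratio <- sd(means100) / sd(means1600)
  expect_gt(ratio, 2)   # expected 4 with wide Monte-Carlo slack
  expect_lt(ratio, 8)
})

test_that("oneCellChiSq follows (O-E)^2/E with a 1-df upper tail", {
  r <- oneCellChiSq(42, 42)
  expect_equal(chiSquare(r), 0)
  expect_equal(pValue(r), 1)
  r2 <- oneCellChiSq(20, 10)
  expect_equal(chiSquare(r2), 10)
  expect_equal(pValue(r2), pchisq(10, 1, lower.tail = FALSE))
  expect_error(oneCellChiSq(5, 0), "> 0")
})

test_that("uniform (unplanted) genomes give a calibrated core-count null", {
  cfg0 <- function(seed) syntheticConfig(
    seed = seed, nChroms = 1L, chromLength = 2e6, nEnhancers = 60L,
    nRepeats = 2000L, enhancerRepeatFold = 1, nGenes = 20L)
  sig <- vapply(1:100, function(s) {
    ann <- generateAnnotations(cfg0(s))
    cls <- classifyRepeats(ann$enhancers, ann$repeats)
    obs <- sum(mcols(cls)$label == "MIR_ENHANCER")
    ex <- expectedCoreCount(ann$enhancers, ann$repeats, ann$layout)
    pValue(oneCellChiSq(obs, ex)) < 0.01
  }, logical(1))
  expect_gte(sum(!sig), 98L)
})

test_that("planted fold-3 genomes recover observed/expected ~ 3", {
  # genome scaled so enhancer spans are a small fraction of the genome
  # (as in real genomes); with a large span share the global repeat
  # density is itself inflated and the ratio is bounded below f
  cfg <- function(seed) syntheticConfig(
    seed = seed, nChroms = 2L, chromLength = 1e8, nEnhancers = 600L,
    nRepeats = 20000L, enhancerRepeatFold = 3, nGenes = 20L)
  ratios <- vapply(1:10, function(s) {
    ann <- generateAnnotations(cfg(s))
    cls <- classifyRepeats(ann$enhancers, ann$repeats)
    obs <- sum(mcols(cls)$label == "MIR_ENHANCER")
    obs / expectedCoreCount(ann$enhancers, ann$repeats, ann$layout)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3) / 3, 0.15)
})
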