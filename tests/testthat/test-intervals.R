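test_that("mergeIntervals unions overlapping and bookended spans", {
  m <- mergeIntervals(granges0(c("chr1", "chr1"), c(0, 5), c(10, 20)))
  expect_equal(start(m) - 1L, 0L)
  expect_equal(end(m), 20L)

  expect_length(mergeIntervals(GRanges()), 0L)

  adj <- mergeIntervals(granges0(c("chr1", "chr1"), c(0, 5), c(5, 10)))
  oracle <- mergeOracle(list(c(0, 5), c(5, 10)), 20)
  expect_equal(cbind(start(adj) - 1L, end(adj)), oracle,
               ignore_attr = TRUE)
})

test_that("mergeIntervals rejects malformed intervals naming the offender", {
  bad <- GRanges("chr1", IRanges(start = 10, width = 0))
  expect_error(mergeIntervals(bad), "malformed.*chr1")
})

test_that("mergeIntervals is idempotent and order-invariant", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:30, 1)
    s <- sample(0:500, n, replace = TRUE)
    gr <- granges0(sample(c("c1", "c2"), n, TRUE), s,
                   s + sample(1:50, n, TRUE))
    m1 <- mergeIntervals(gr)
    expect_identical(granges(mergeIntervals(m1)), granges(m1))
    m2 <- mergeIntervals(gr[sample(n)])
    expect_identical(granges(m2), granges(m1))
  }
})

test_that("occupiedFraction matches its closed-form examples", {
  expect_equal(occupiedFraction(granges0("chr1", 0, 100),
                                granges0("chr1", 10, 20)), 0.10)
  expect_equal(occupiedFraction(granges0("chr1", 0, 100), GRanges()), 0)
  expect_equal(occupiedFraction(granges0("chr1", 0, 100),
                                granges0("chr1", 0, 200)), 1.0)
  expect_error(occupiedFraction(GRanges(), granges0("chr1", 0, 10)),
               "non-empty")
})

test_that("occupiedFraction equals a per-base boolean-array oracle", {
  set.seed(42)
  for (i in 1:200) {
    chromLen <- sample(200:10000, 1)
    nr <- sample(1:8, 1); nf <- sample(0:12, 1)
    rs <- sample(0:(chromLen - 60), nr, replace = TRUE)
    regions0 <- lapply(rs, function(s) c(s, s + sample(1:50, 1)))
    features0 <- if (nf) {
      fs <- sample(0:(chromLen - 60), nf, replace = TRUE)
      lapply(fs, function(s) c(s, s + sample(1:50, 1)))
    } else list()
    regions <- granges0("chr1", vapply(regions0, `[`, 0, 1),
                        vapply(regions0, `[`, 0, 2))
    features <- if (nf)
      granges0("chr1", vapply(features0, `[`, 0, 1),
               vapply(features0, `[`, 0, 2)) else GRanges()
    want <- if (nf) occupancyOracle(regions0, features0, chromLen) else 0
    expect_equal(occupiedFraction(regions, features), want,
                 tolerance = 1e-12)
  }
})

test_that("sampleBackground places windows in the downstream envelope", {
  layout <- toyLayout()
  # envelope width forced to zero: locus length equals the offset
  locus <- granges0("chrA", 1000, 1100)
  w <- sampleBackground(locus, layout, offsetBp = 100L, seed = 5)
  expect_equal(start(w) - 1L, end(locus) + 100L)
  expect_equal(width(w), width(locus))

  # determinism
  locus2 <- granges0("chrA", 5000, 5200)
  w1 <- sampleBackground(locus2, layout, seed = 99)
  w2 <- sampleBackground(locus2, layout, seed = 99)
  expect_identical(start(w1), start(w2))

  # general placement bounds: start in [end+offset, end+2*offset-len]
  set.seed(1)
  for (s in 1:50) {
    w <- sampleBackground(locus2, layout, offsetBp = 10000L, seed = s)
    s0 <- start(w) - 1L
    expect_gte(s0, 5200 + 10000)
    expect_lte(s0, 5200 + 20000 - 200)
  }
})

test_that("sampleBackground draws uniformly over the envelope", {
  layout <- toyLayout()
  locus <- granges0("chrA", 5000, 5100)
  offset <- 10000L
  lo <- 5100 + offset
  hi <- 5100 + 2L * offset - 100L
  starts <- vapply(1:1000, function(s)
    start(sampleBackground(locus, layout, offsetBp = offset, seed = s)) - 1L,
    integer(1))
  expect_true(all(starts >= lo & starts <= hi))
  bins <- cut(starts, breaks = seq(lo - 0.5, hi + 0.5, length.out = 11))
  gof <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.01)
})

test_that("sampleBackground mirrors upstream at chromosome ends and skips infeasible loci", {
  layout <- GenomeInfoDb::Seqinfo(seqnames = "chrS", seqlengths = 500000L)
  # locus near the right end: downstream envelope exceeds the chromosome
  locus <- granges0("chrS", 450000, 450100)
  w <- sampleBackground(locus, layout, offsetBp = 100000L, seed = 3)
  s0 <- start(w) - 1L
  expect_gte(s0, 450000 - 200000)
  expect_lte(s0 + 100, 450000 - 100000)

  # chromosome too short for either placement
  shortLayout <- GenomeInfoDb::Seqinfo(seqnames = "chrT", seqlengths = 50000L)
  expect_warning(
    w2 <- sampleBackground(granges0("chrT", 20000, 20100), shortLayout,
                           offsetBp = 100000L, seed = 1),
    "skipped")
  expect_length(w2, 0L)
})

test_that("normalizedLocalEnrichment is ~1 for uniform features and recovers a planted fold", {
  layout <- GenomeInfoDb::Seqinfo(seqnames = "chrU", seqlengths = 20000000L)
  # 40 regions of 50 kb spaced 500 kb apart: background envelopes
  # (100-200 kb downstream) never touch a neighbouring region
  rs <- seq(100000L, by = 500000L, length.out = 40L)
  regions <- granges0("chrU", rs, rs + 50000L)
  regionLen <- 50000L

  # uniform null: fold estimated as the mean of 3 independent draws of
  # 10,000 features each
  folds <- vapply(1:3, function(r) {
    set.seed(700 + r)
    fs <- sample.int(19999000L, 10000L) - 1L
    features <- granges0("chrU", fs, fs + 100L)
    normalizedLocalEnrichment(regions, features, layout,
                              nBackground = 3L, seed = r)
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.05)

  # features planted at 1.26x density inside the regions
  share <- length(rs) * regionLen / 20000000
  pIn <- 1.26 * share / (1.26 * share + (1 - share))
  folds2 <- vapply(1:3, function(r) {
    set.seed(780 + r)
    n <- 8000L
    inRegion <- runif(n) < pIn
    pos <- integer(n)
    pick <- sample(length(rs), sum(inRegion), replace = TRUE)
    pos[inRegion] <- rs[pick] + sample.int(regionLen, sum(inRegion), TRUE) - 1L
    nOut <- sum(!inRegion)
    cand <- sample.int(19999000L, 3L * nOut) - 1L
    bin <- findInterval(cand, as.vector(rbind(rs, rs + regionLen)))
    cand <- cand[bin %% 2L == 0L]  # outside every region
    pos[!inRegion] <- cand[seq_len(nOut)]
    planted <- granges0("chrU", pos, pos + 100L)
    normalizedLocalEnrichment(regions, planted, layout,
                              nBackground = 3L, seed = 10 + r)
  }, numeric(1))
  expect_lt(abs(mean(folds2) - 1.26), 0.1)

  # all features inside the regions: zero background density
  inside <- granges0("chrU", rs + 100L, rs + 300L)
  expect_error(normalizedLocalEnrichment(regions, inside, layout, seed = 1),
               "zero")
  expect_identical(
    normalizedLocalEnrichment(regions, inside, layout, seed = 1,
                              infAsError = FALSE), Inf)
})

test_that("featureDensityFold measures a planted start-density ratio", {
  layout <- GenomeInfoDb::Seqinfo(seqnames = "chrV", seqlengths = 2000000L)
  regions <- granges0("chrV", c(100000, 700000), c(150000, 750000))
  set.seed(5)
  # density ratio 4 inside vs outside by construction
  nIn <- 4000; nOut <- 19000  # 4000/1e5 vs 19000/1.9e6 -> ratio 4
  posIn <- c(sample(100000:149999, nIn / 2, TRUE),
             sample(700000:749999, nIn / 2, TRUE))
  posOut <- sample(c(0:99999, 150000:699999, 750000:1999000), nOut, TRUE)
  feats <- granges0("chrV", c(posIn, posOut), c(posIn, posOut) + 100L)
  fold <- featureDensityFold(regions, feats, layout)
  expect_lt(abs(fold - 4) / 4, 0.1)
})
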