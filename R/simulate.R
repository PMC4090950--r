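#' Configuration for the synthetic-data generator
#'
#' Defines a toy genome and the planted statistical structure every
#' pipeline stage is tested against: repeats at elevated density inside
#' enhancer spans, enhancer-centered signal bumps for active chromatin
#' marks and a depletion for a repressive mark, motif instances planted
#' at a higher rate in enhancer-associated repeat sequences, and an
#' expression matrix whose tissue specificity is coupled to local
#' enhancer-repeat density.
#'
#' Defaults describe a 2 x 5 Mb genome with 200 enhancers, 5,000
#' repeats, 500 genes and 6 tissues — large enough for all planted
#' effects to be recoverable, small enough for the full pipeline to run
#' in well under two minutes on one CPU.
#'
#' @param seed integer seed; every generator is a pure function of the
#'   config, so identical configs give identical output.
#' @param nChroms,chromLength genome layout.
#' @param nEnhancers enhancer anchors, placed uniformly with >= 8 kb
#'   spacing.
#' @param nRepeats repeat annotations.
#' @param repeatLengthMedian,repeatLengthSigma log-normal repeat length
#'   distribution (median bp and log-sd); lengths are floored at 50 bp.
#' @param enhancerRepeatFold planted density ratio of repeats inside
#'   enhancer spans relative to outside (`f >= 1`; 1 = no enrichment).
#' @param bumpHeight target central-window fold enrichment of active
#'   marks at enhancers (1 = flat).
#' @param bumpSigma Gaussian width (bp) of the planted signal bump.
#' @param depletionDepth multiplicative floor of the repressive mark at
#'   enhancer anchors (0.2 = signal reduced to 20%).
#' @param tagRate expected background tags per bp of each track.
#' @param nGenes,nTissues expression matrix dimensions.
#' @param tsDensityBeta coupling strength between a gene's
#'   tissue-specificity and its local enhancer-repeat density (0 =
#'   independent).
#' @param motif motif string planted in repeat sequences.
#' @param motifPlantRateTarget,motifPlantRateBackground planting
#'   probability per sequence for enhancer-associated and other
#'   repeats.
#' @param gcContent GC fraction of background sequence.
#' @return A `SyntheticConfig` (validated list).
#' @export
syntheticConfig <- function(seed = 1L,
                            nChroms = 2L, chromLength = 5e6,
                            nEnhancers = 200L,
                            nRepeats = 5000L,
                            repeatLengthMedian = 180,
                            repeatLengthSigma = 0.5,
                            enhancerRepeatFold = 3,
                            bumpHeight = 5,
                            bumpSigma = 1000,
                            depletionDepth = 0.2,
                            tagRate = 0.01,
                            nGenes = 500L,
                            nTissues = 6L,
                            tsDensityBeta = 0.8,
                            motif = "TGACTCA",
                            motifPlantRateTarget = 0.5,
                            motifPlantRateBackground = 0.05,
                            gcContent = 0.41) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = as.integer(chromLength),
              nEnhancers = as.integer(nEnhancers),
              nRepeats = as.integer(nRepeats),
              repeatLengthMedian = repeatLengthMedian,
              repeatLengthSigma = repeatLengthSigma,
              enhancerRepeatFold = enhancerRepeatFold,
              bumpHeight = bumpHeight, bumpSigma = bumpSigma,
              depletionDepth = depletionDepth, tagRate = tagRate,
              nGenes = as.integer(nGenes), nTissues = as.integer(nTissues),
              tsDensityBeta = tsDensityBeta, motif = toupper(motif),
              motifPlantRateTarget = motifPlantRateTarget,
              motifPlantRateBackground = motifPlantRateBackground,
              gcContent = gcContent)
  stopifnot(cfg$nChroms >= 1L, cfg$chromLength > 0L,
            cfg$nEnhancers >= 0L, cfg$nRepeats >= 0L,
            cfg$enhancerRepeatFold >= 1,
            cfg$depletionDepth >= 0, cfg$depletionDepth <= 1,
            cfg$motifPlantRateTarget >= 0, cfg$motifPlantRateTarget <= 1,
            cfg$motifPlantRateBackground >= 0,
            cfg$motifPlantRateBackground <= 1,
            cfg$gcContent > 0, cfg$gcContent < 1,
            cfg$tsDensityBeta >= 0)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# n sorted positions on [lo, hi] with pairwise gaps >= minGap, uniform
# over all feasible placements.
spacedPositions <- function(n, lo, hi, minGap) {
  if (n == 0L) return(integer(0))
  slack <- (hi - lo) - (n - 1L) * minGap
  if (slack < 0)
    stop("infeasible packing: ", n, " features with spacing ", minGap,
         " do not fit in ", hi - lo, " bp")
  u <- sort(runif(n, 0, slack))
  as.integer(round(lo + u + (seq_len(n) - 1L) * minGap))
}

# Split n features across chromosomes proportionally to length.
allocateToChroms <- function(n, lens) {
  frac <- lens / sum(lens)
  base <- floor(n * frac)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * frac - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a synthetic genome layout with enhancers, repeats and genes
#'
#' Enhancer anchors are uniform with a minimum spacing of 8 kb (one
#' span width) and a 25 kb margin from chromosome ends so spans and
#' profile windows stay in bounds. Repeat start positions are drawn
#' from a two-component mixture putting `enhancerRepeatFold` times the
#' background density inside enhancer spans. Gene bodies are
#' non-overlapping.
#'
#' @param config a [syntheticConfig()].
#' @return List with elements `layout` (`Seqinfo`), `enhancers`
#'   ([EnhancerSet]), `repeats` (`GRanges` with `id` and `family`
#'   metadata) and `genes` (`GRanges` with ids in `names`).
#' @export
generateAnnotations <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  lens <- rep(config$chromLength, config$nChroms)
  chroms <- paste0("chr", seq_len(config$nChroms))
  layout <- Seqinfo(seqnames = chroms, seqlengths = lens)
  withSeed(childSeed(config$seed, 1L), {
    margin <- 25000L
    nPer <- allocateToChroms(config$nEnhancers, lens)
    anchorPos <- lapply(seq_along(chroms), function(i)
      spacedPositions(nPer[i], margin, lens[i] - margin, 8000L))
    anchors <- GRanges(rep(chroms, lengths(anchorPos)),
                       IRanges(unlist(anchorPos) + 1L, width = 1L),
                       seqinfo = layout)
    enhancers <- EnhancerSet(anchors)
    spans <- suppressMessages(enhancerSpans(enhancers))

    repLen <- pmax(50L, as.integer(round(rlnorm(
      config$nRepeats, log(config$repeatLengthMedian),
      config$repeatLengthSigma))))
    repStart <- placeWeighted(config$nRepeats, spans, layout,
                              config$enhancerRepeatFold)
    chromLen <- lens[match(repStart$chrom, chroms)]
    s <- pmin(repStart$pos, chromLen - repLen)  # keep repeat on-chromosome
    s <- pmax(s, 1L)
    repeats <- GRanges(repStart$chrom, IRanges(s, width = repLen),
                       seqinfo = layout)
    names(repeats) <- sprintf("MIR%06d", seq_along(repeats))
    mcols(repeats)$family <- "MIR"

    nGPer <- allocateToChroms(config$nGenes, lens)
    geneLen <- as.integer(round(runif(config$nGenes, 2000, 10000)))
    genes <- GRanges(seqinfo = layout)
    off <- 0L
    for (i in seq_along(chroms)) {
      if (nGPer[i] == 0L) next
      li <- geneLen[(off + 1L):(off + nGPer[i])]
      gs <- spacedPositions(nGPer[i], 1000L, lens[i] - max(li) - 1000L,
                            max(li) + 500L)
      genes <- c(genes, GRanges(chroms[i], IRanges(gs + 1L, width = li),
                                seqinfo = layout))
      off <- off + nGPer[i]
    }
    names(genes) <- sprintf("gene%04d", seq_along(genes))
    list(layout = layout, enhancers = enhancers, repeats = repeats,
         genes = genes)
  })
}

# Draw n 1-based start positions with relative density `fold` inside
# `spans` and 1 elsewhere.
placeWeighted <- function(n, spans, layout, fold) {
  lens <- seqlengths(layout)
  G <- sum(as.numeric(lens))
  spans <- reduce(spans, ignore.strand = TRUE)
  S <- sum(as.numeric(width(spans)))
  pSpan <- fold * S / (fold * S + (G - S))
  inSpan <- runif(n) < pSpan
  chrom <- character(n); pos <- integer(n)
  nIn <- sum(inSpan)
  if (nIn > 0L) {
    w <- as.numeric(width(spans))
    pick <- sample.int(length(spans), nIn, replace = TRUE, prob = w)
    off <- floor(runif(nIn) * w[pick])
    chrom[inSpan] <- as.character(seqnames(spans))[pick]
    pos[inSpan] <- start(spans)[pick] + as.integer(off)
  }
  nOut <- n - nIn
  if (nOut > 0L) {
    # complement of the spans, per chromosome
    gaps <- setdiff(GRanges(seqnames(layout),
                            IRanges(1L, seqlengths(layout)),
                            seqinfo = layout),
                    spans, ignore.strand = TRUE)
    w <- as.numeric(width(gaps))
    pick <- sample.int(length(gaps), nOut, replace = TRUE, prob = w)
    off <- floor(runif(nOut) * w[pick])
    chrom[!inSpan] <- as.character(seqnames(gaps))[pick]
    pos[!inSpan] <- start(gaps)[pick] + as.integer(off)
  }
  list(chrom = chrom, pos = pos)
}

#' Generate per-mark synthetic signal tracks
#'
#' Active marks are uniform Poisson background plus a Gaussian-shaped
#' tag surplus centered on each enhancer anchor, calibrated so that the
#' central 500 bp metaprofile window reaches `bumpHeight`-fold
#' enrichment over the track's own genome average. The repressive mark
#' is uniform background thinned multiplicatively around anchors down
#' to `depletionDepth` at the anchor.
#'
#' @param config a [syntheticConfig()].
#' @param enhancers the [EnhancerSet] from [generateAnnotations()].
#' @param layout the genome `Seqinfo`.
#' @param marks named character vector mapping mark names to
#'   `"active"` or `"repressive"`.
#' @return Named list of [SignalTrack]s.
#' @export
generateTracks <- function(config, enhancers, layout,
                           marks = c(H3K4me1 = "active",
                                     H3K27ac = "active",
                                     H3K27me3 = "repressive")) {
  stopifnot(inherits(config, "SyntheticConfig"))
  lens <- seqlengths(layout)
  G <- sum(as.numeric(lens))
  a <- anchors(enhancers)
  nE <- length(a)
  window <- 500
  out <- vector("list", length(marks))
  names(out) <- names(marks)
  for (mi in seq_along(marks)) {
    out[[mi]] <- withSeed(childSeed(config$seed, 10L + mi), {
      # uniform background
      nBg <- rpois(length(lens), config$tagRate * as.numeric(lens))
      bgChrom <- rep(seqnames(layout), nBg)
      bgPos <- unlist(lapply(seq_along(lens), function(i)
        sample.int(lens[i], nBg[i], replace = TRUE)), use.names = FALSE)
      pos <- GRanges(bgChrom, IRanges(bgPos, width = 1L), seqinfo = layout)
      if (marks[mi] == "active" && config$bumpHeight > 1 && nE > 0L) {
        # surplus per enhancer solved so the central window's fold over
        # the track's own genome average equals bumpHeight
        h <- config$bumpHeight
        mC <- pnorm(window / 2, 0, config$bumpSigma) -
              pnorm(-window / 2, 0, config$bumpSigma)
        denom <- mC - h * window * nE / G
        if (denom <= 0)
          stop("bump too high for this genome size: increase genome or lower bumpHeight")
        nS <- config$tagRate * window * (h - 1) / denom
        k <- rpois(nE, nS)
        offs <- round(rnorm(sum(k), 0, config$bumpSigma))
        bumpChrom <- rep(as.character(seqnames(a)), k)
        bumpPos <- rep(start(a), k) + as.integer(offs)
        bumpPos <- pmax(1L, pmin(bumpPos, lens[bumpChrom]))
        pos <- c(pos, GRanges(bumpChrom, IRanges(bumpPos, width = 1L),
                              seqinfo = layout))
      } else if (marks[mi] == "repressive" && config$depletionDepth < 1 &&
                 nE > 0L) {
        d <- distanceToNearest(pos, a, ignore.strand = TRUE)
        dist <- rep(Inf, length(pos))
        dist[queryHits(d)] <- mcols(d)$distance
        keepProb <- 1 - (1 - config$depletionDepth) *
          exp(-dist^2 / (2 * config$bumpSigma^2))
        pos <- pos[runif(length(pos)) < keepProb]
      }
      SignalTrack(sort(pos), weight = 1, layout = layout)
    })
  }
  out
}

#' Generate a synthetic genes-by-tissues expression matrix
#'
#' Each gene's across-tissue profile is Dirichlet-distributed with a
#' symmetric concentration parameter that decreases with the gene's
#' enhancer-repeat density: low concentration yields sparse,
#' tissue-specific profiles, so tissue specificity rises with density
#' at a rate controlled by `tsDensityBeta` (`beta = 0` gives
#' independence). Overall magnitudes are log-normal.
#'
#' @param config a [syntheticConfig()].
#' @param genes `GRanges` of genes (ids in names).
#' @param densities per-gene feature densities (same order as `genes`),
#'   e.g. from [geneFeatureDensity()].
#' @return Nonnegative matrix, genes x tissues.
#' @export
generateExpression <- function(config, genes, densities) {
  stopifnot(inherits(config, "SyntheticConfig"),
            length(genes) == length(densities))
  n <- length(genes); nT <- config$nTissues
  withSeed(childSeed(config$seed, 30L), {
    dmax <- max(densities)
    dScaled <- if (dmax > 0) densities / dmax else rep(0, n)
    # concentration falls from alphaMax toward 0 as beta * density grows
    alpha <- 4 * exp(-4 * config$tsDensityBeta * dScaled) *
      exp(rnorm(n, 0, 0.25))
    w <- matrix(rgamma(n * nT, shape = rep(alpha, nT)), nrow = n)
    zero <- rowSums(w) == 0
    if (any(zero))  # numeric underflow at tiny alpha: point mass
      w[cbind(which(zero), sample.int(nT, sum(zero), replace = TRUE))] <- 1
    w <- w / rowSums(w)
    m <- rlnorm(n, log(300), 0.6)
    expr <- w * m
    dimnames(expr) <- list(repeatIds(genes),
                           sprintf("tissue%02d", seq_len(nT)))
    expr
  })
}

#' Generate synthetic repeat sequences with planted motifs
#'
#' I.i.d. background nucleotides at the configured GC content, with the
#' configured motif string planted (at a uniform random offset) with
#' probability `motifPlantRateTarget` in enhancer-associated repeats
#' (labels `MIR_ENHANCER`/`ENHANCER_MIR`) and
#' `motifPlantRateBackground` elsewhere. Repeats shorter than the motif
#' are skipped with a warning.
#'
#' @param config a [syntheticConfig()].
#' @param repeats `GRanges` of repeats (lengths give sequence lengths).
#' @param labels classification labels aligned with `repeats` (e.g. the
#'   `label` column from [classifyRepeats()]).
#' @return A `DNAStringSet` named by repeat id.
#' @export
generateSequences <- function(config, repeats, labels) {
  stopifnot(inherits(config, "SyntheticConfig"),
            length(repeats) == length(labels))
  gc <- config$gcContent
  baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  motif <- config$motif
  mLen <- nchar(motif)
  lens <- width(repeats)
  isTarget <- labels %in% c("MIR_ENHANCER", "ENHANCER_MIR")
  withSeed(childSeed(config$seed, 40L), {
    rate <- ifelse(isTarget, config$motifPlantRateTarget,
                   config$motifPlantRateBackground)
    plant <- runif(length(repeats)) < rate
    tooShort <- plant & lens < mLen
    if (any(tooShort)) {
      warning(sum(tooShort), " repeat(s) shorter than the motif: ",
              "planting skipped")
      plant[tooShort] <- FALSE
    }
    # one background draw for all sequences, then split by length
    allBases <- sample(names(baseProb), sum(lens), replace = TRUE,
                       prob = baseProb)
    ends <- cumsum(lens)
    seqs <- substring(paste(allBases, collapse = ""),
                      c(1L, head(ends, -1L) + 1L), ends)
    at <- ifelse(plant, 1L, NA_integer_)
    idx <- which(plant)
    at[idx] <- 1L + floor(runif(length(idx)) * (lens[idx] - mLen + 1L))
    for (i in idx)
      substr(seqs[i], at[i], at[i] + mLen - 1L) <- motif
    out <- DNAStringSet(seqs)
    names(out) <- repeatIds(repeats)
    out
  })
}

#' Write a full synthetic dataset to disk
#'
#' Generates annotations, tracks, sequences and expression for a config
#' and writes them in plain-text formats (BED, tag BED, FASTA, TSV,
#' chrom.sizes) under `dir`.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
writeSyntheticData <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- generateAnnotations(config)
  cls <- classifyRepeats(ann$enhancers, ann$repeats)
  tracks <- generateTracks(config, ann$enhancers, ann$layout)
  dens <- geneFeatureDensity(
    ann$genes, cls[mcols(cls)$label != "NON_ENHANCER_MIR"])
  expr <- generateExpression(config, ann$genes, mcols(dens)$density)
  seqs <- generateSequences(config, ann$repeats, mcols(cls)$label)

  paths <- list(sizes = file.path(dir, "genome.sizes"),
                enhancers = file.path(dir, "enhancers.bed"),
                repeats = file.path(dir, "repeats.bed"),
                genes = file.path(dir, "genes.bed"),
                expression = file.path(dir, "expression.tsv"),
                sequences = file.path(dir, "repeats.fa"))
  writeChromSizes(ann$layout, paths$sizes)
  a <- anchors(ann$enhancers)
  mcols(a)$name <- names(a)
  writeBed(a, paths$enhancers)
  r <- ann$repeats
  mcols(r)$name <- names(r)
  writeBed(r, paths$repeats)
  g <- ann$genes
  mcols(g)$name <- names(g)
  writeBed(g, paths$genes)
  writeExpressionMatrix(expr, paths$expression)
  writeXStringSet(seqs, paths$sequences)
  for (mk in names(tracks)) {
    p <- file.path(dir, paste0(mk, ".tags.bed"))
    writeSignalTrack(tracks[[mk]], p)
    paths[[paste0("track_", mk)]] <- p
  }
  invisible(paths)
}
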