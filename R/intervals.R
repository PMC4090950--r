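#' Merge genomic intervals into a disjoint sorted union
#'
#' Overlapping and bookended intervals are merged; the result covers
#' exactly the union of input basepairs. Strand is ignored: none of the
#' overlap computations in this package condition on strand.
#'
#' @param x a [GenomicRanges::GRanges].
#' @return A sorted, disjoint `GRanges`.
#' @export
#' @examples
#' mergeIntervals(granges0(c("chr1", "chr1"), c(0, 5), c(10, 20)))
mergeIntervals <- function(x) {
  stopifnot(is(x, "GRanges"))
  bad <- which(width(x) < 1L)
  if (length(bad))
    stop("malformed interval (start >= end): ",
         as.character(x[bad[1L]]))
  reduce(sortSeqlevels(x), ignore.strand = TRUE)
}

#' Fraction of region basepairs occupied by features
#'
#' The occupancy density used throughout: the total number of basepairs
#' of the (merged) features that fall inside the (merged) regions,
#' divided by the total merged region length. Features overhanging a
#' region boundary contribute only their overlapping basepairs, so the
#' result always lies in `[0, 1]`.
#'
#' @param regions non-empty `GRanges` of query regions.
#' @param features `GRanges` of features (e.g. repeat annotations).
#' @return The occupied fraction, a number in `[0, 1]`.
#' @export
#' @examples
#' occupiedFraction(granges0("chr1", 0, 100), granges0("chr1", 10, 20))
occupiedFraction <- function(regions, features) {
  if (!is(regions, "GRanges") || length(regions) == 0L)
    stop("regions must be a non-empty GRanges")
  mr <- mergeIntervals(regions)
  if (length(features) == 0L) return(0)
  mf <- mergeIntervals(features)
  ov <- suppressWarnings(intersect(mr, mf, ignore.strand = TRUE))
  sum(as.numeric(width(ov))) / sum(as.numeric(width(mr)))
}

#' Density fold of features inside regions versus the rest of the genome
#'
#' Ratio of the per-bp feature density inside the (merged) regions to
#' the density over the remainder of the genome. With `by = "count"`
#' (default) each feature is assigned to one side by its start
#' position, which measures a placement process directly and does not
#' saturate when features are dense; `by = "occupancy"` uses occupied
#' basepair fractions instead (see [occupiedFraction()]).
#'
#' @param regions non-empty `GRanges`.
#' @param features `GRanges` of features.
#' @param layout `Seqinfo` with chromosome lengths.
#' @param by `"count"` or `"occupancy"`.
#' @return Fold (positive number, possibly `Inf` when no feature lies
#'   outside the regions).
#' @export
featureDensityFold <- function(regions, features, layout,
                               by = c("count", "occupancy")) {
  by <- match.arg(by)
  if (length(regions) == 0L) stop("regions must be non-empty")
  mr <- mergeIntervals(regions)
  genome <- GRanges(seqnames(layout), IRanges(1L, seqlengths(layout)),
                    seqinfo = layout)
  rest <- setdiff(genome, mr, ignore.strand = TRUE)
  if (by == "occupancy") {
    dIn <- occupiedFraction(mr, features)
    dOut <- occupiedFraction(rest, features)
  } else {
    starts <- resize(features, width = 1L, fix = "start", ignore.strand = TRUE)
    dIn <- sum(countOverlaps(mr, starts)) / sum(as.numeric(width(mr)))
    dOut <- sum(countOverlaps(rest, starts)) / sum(as.numeric(width(rest)))
  }
  if (dOut == 0) return(Inf)
  dIn / dOut
}

# 0-based coordinates of a single locus.
locus0 <- function(gr) list(chrom = as.character(seqnames(gr)),
                            s0 = start(gr) - 1L, e0 = end(gr))

#' Sample a local background window for a locus
#'
#' Draws a same-length control window downstream of the locus: the
#' window start is uniform over the envelope beginning `offsetBp`
#' downstream of the locus end and ending `2 * offsetBp` downstream.
#' When the downstream envelope runs off the chromosome the placement is
#' mirrored upstream of the locus start. Loci for which neither
#' placement fits are skipped with a warning (an `NA` entry).
#'
#' @param loci `GRanges` of loci of interest.
#' @param layout `Seqinfo` with chromosome lengths.
#' @param offsetBp distance (bp) separating locus and background
#'   envelope; default 100 kb.
#' @param seed optional integer seed for reproducible draws.
#' @return `GRanges` of background windows, one per feasible locus; the
#'   `locusIndex` metadata column maps windows back to input loci.
#' @export
sampleBackground <- function(loci, layout, offsetBp = 100000L, seed = NULL) {
  stopifnot(is(loci, "GRanges"), is(layout, "Seqinfo"))
  offsetBp <- as.integer(offsetBp)
  lens <- seqlengths(layout)
  withSeed(seed, {
    starts0 <- rep(NA_integer_, length(loci))
    for (i in seq_along(loci)) {
      l <- locus0(loci[i])
      if (!l$chrom %in% names(lens) || is.na(lens[l$chrom]))
        stop("locus on chromosome absent from layout: ", l$chrom)
      G <- lens[[l$chrom]]
      L <- l$e0 - l$s0
      lo <- l$e0 + offsetBp
      hi <- l$e0 + 2L * offsetBp - L
      if (hi >= lo && hi + L <= G) {
        starts0[i] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      } else {
        lo.u <- l$s0 - 2L * offsetBp
        hi.u <- l$s0 - offsetBp - L
        if (hi.u >= lo.u && lo.u >= 0L) {
          starts0[i] <- lo.u + sample.int(hi.u - lo.u + 1L, 1L) - 1L
        } else {
          warning("chromosome too short for background placement; ",
                  "locus skipped: ", as.character(loci[i]))
        }
      }
    }
    keep <- which(!is.na(starts0))
    out <- GRanges(seqnames(loci)[keep],
                   IRanges(starts0[keep] + 1L, width = width(loci)[keep]),
                   seqinfo = layout[seqlevels(loci)])
    mcols(out)$locusIndex <- keep
    out
  })
}

#' Fold enrichment of features in regions over local backgrounds
#'
#' Density (occupied fraction) of features inside the regions divided by
#' their density inside same-length background windows sampled ~100 kb
#' downstream of each region. A fold of 1 signals no local enrichment.
#' Normalizing both terms by the genome-wide average density leaves the
#' ratio unchanged, so no explicit genome normalization is applied.
#'
#' @param regions non-empty `GRanges`.
#' @param features `GRanges` of features.
#' @param layout `Seqinfo` with chromosome lengths.
#' @param offsetBp background offset, see [sampleBackground()].
#' @param nBackground background windows drawn per region.
#' @param seed integer seed for the background draws.
#' @param infAsError if `TRUE` (default) a zero background density is an
#'   error; otherwise `Inf` is returned as a sentinel.
#' @return Fold enrichment (positive number, possibly `Inf`).
#' @export
normalizedLocalEnrichment <- function(regions, features, layout,
                                      offsetBp = 100000L, nBackground = 1L,
                                      seed = NULL, infAsError = TRUE) {
  if (length(regions) == 0L) stop("regions must be non-empty")
  bg <- do.call(c, lapply(seq_len(nBackground), function(j)
    sampleBackground(regions, layout, offsetBp = offsetBp,
                     seed = childSeed(seed, j))))
  if (length(bg) == 0L) stop("no feasible background window for any region")
  dReg <- occupiedFraction(regions, features)
  dBg <- occupiedFraction(bg, features)
  if (dBg == 0) {
    if (infAsError)
      stop("background feature density is zero: fold enrichment undefined")
    return(Inf)
  }
  dReg / dBg
}
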