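#' @title Core S4 classes
#' @description S4 containers used across the pipeline stages.
#' @name enhancerTE-classes
NULL

#' EnhancerSet: chromatin-predicted enhancers anchored at single basepairs
#'
#' Each enhancer is predicted at a single anchor basepair; its functional
#' span is taken to be the +/- 4 kb region around the anchor (the
#' empirical extent of the enhancer-characteristic chromatin pattern) and
#' its core the central 200 bp. Spans and cores are derived on demand and
#' clipped at chromosome ends when sequence lengths are known.
#'
#' @slot anchors width-1 [GenomicRanges::GRanges] of anchor positions;
#'   names are enhancer identifiers.
#' @slot spanHalfWidth half-width of the enhancer span in bp (default 4000).
#' @slot coreHalfWidth half-width of the enhancer core in bp (default 100).
#' @export
setClass("EnhancerSet",
  representation(anchors = "GRanges",
                 spanHalfWidth = "integer",
                 coreHalfWidth = "integer"))

setValidity("EnhancerSet", function(object) {
  a <- object@anchors
  if (length(a) && any(width(a) != 1L))
    return("anchors must be width-1 positions")
  if (object@spanHalfWidth <= 0L || object@coreHalfWidth <= 0L)
    return("half-widths must be positive")
  if (object@coreHalfWidth > object@spanHalfWidth)
    return("core must lie within the span")
  sl <- seqlengths(a)
  if (length(a) && !all(is.na(sl))) {
    len <- sl[as.character(seqnames(a))]
    if (any(!is.na(len) & (start(a) < 1L | start(a) > len)))
      return("anchor outside chromosome bounds")
  }
  TRUE
})

#' Construct an EnhancerSet
#'
#' @param anchors either a width-1 `GRanges` of anchor positions, or a
#'   character vector of chromosome names (with `pos0` giving 0-based
#'   anchor offsets, as in a `chrom<TAB>anchor` table).
#' @param pos0 0-based anchor basepair offsets when `anchors` is a
#'   character vector of chromosome names.
#' @param layout optional [GenomeInfoDb::Seqinfo] giving chromosome
#'   lengths (enables clipping of derived spans).
#' @param spanHalfWidth,coreHalfWidth half-widths (bp) of the derived
#'   span and core windows.
#' @param ids enhancer identifiers; defaults to `enh<k>`.
#' @return An `EnhancerSet`.
#' @export
#' @examples
#' es <- EnhancerSet("chr1", pos0 = 50000)
#' enhancerSpans(es)
EnhancerSet <- function(anchors, pos0 = NULL, layout = NULL,
                        spanHalfWidth = 4000L, coreHalfWidth = 100L,
                        ids = NULL) {
  if (is.character(anchors)) {
    if (is.null(pos0)) stop("pos0 required when anchors given as chromosome names")
    anchors <- GRanges(anchors, IRanges(as.integer(pos0) + 1L, width = 1L))
  }
  if (!is(anchors, "GRanges")) stop("anchors must be a GRanges or chromosome names")
  if (!is.null(layout)) seqinfo(anchors) <- layout[seqlevels(anchors)]
  if (is.null(ids)) ids <- names(anchors)
  if (is.null(ids)) ids <- sprintf("enh%05d", seq_along(anchors))
  names(anchors) <- ids
  new("EnhancerSet", anchors = anchors,
      spanHalfWidth = as.integer(spanHalfWidth),
      coreHalfWidth = as.integer(coreHalfWidth))
}

#' @describeIn EnhancerSet anchor positions (width-1 `GRanges`).
#' @param x an `EnhancerSet`.
#' @export
anchors <- function(x) x@anchors

derivedWindows <- function(x, halfWidth) {
  a <- x@anchors
  # anchor at 1-based position p covers 0-based offset p-1; the +/- h
  # window is 0-based [p-1-h, p-1+h), i.e. 1-based [p-h, p+h-1].
  w <- GRanges(seqnames(a), IRanges(start(a) - halfWidth,
                                    start(a) + halfWidth - 1L),
               seqinfo = seqinfo(a))
  names(w) <- names(a)
  clipped <- suppressWarnings(trim(w))
  clipped <- restrict(clipped, start = 1L)
  nclip <- sum(width(clipped) != width(w))
  if (nclip) message(nclip, " window(s) clipped at chromosome ends")
  clipped
}

#' @describeIn EnhancerSet the +/- `spanHalfWidth` spans, clipped at
#'   chromosome ends (clipping is reported via a message).
#' @export
enhancerSpans <- function(x) derivedWindows(x, x@spanHalfWidth)

#' @describeIn EnhancerSet the central core windows (default 200 bp).
#' @export
enhancerCores <- function(x) derivedWindows(x, x@coreHalfWidth)

#' @export
setMethod("length", "EnhancerSet", function(x) length(x@anchors))

setMethod("show", "EnhancerSet", function(object) {
  cat("EnhancerSet with", length(object), "enhancers",
      sprintf("(span %d bp, core %d bp)\n",
              2L * object@spanHalfWidth, 2L * object@coreHalfWidth))
  if (length(object)) show(head(object@anchors, 3L))
})

#' SignalTrack: genome-wide tag positions with weights
#'
#' A sequencing signal track reduced to the point model used throughout:
#' each tag is assigned to a single basepair (its start coordinate), with
#' an optional weight (a bedGraph interval of value v contributes one
#' position of weight v).
#'
#' @slot tags width-1 `GRanges` of tag positions with a numeric `weight`
#'   metadata column.
#' @export
setClass("SignalTrack", representation(tags = "GRanges"))

setValidity("SignalTrack", function(object) {
  t <- object@tags
  if (length(t) && any(width(t) != 1L)) return("tags must be width-1 positions")
  if (is.null(mcols(t)$weight)) return("tags need a 'weight' metadata column")
  if (any(mcols(t)$weight < 0)) return("negative tag weight")
  if (all(is.na(seqlengths(t)))) return("SignalTrack requires chromosome lengths (seqinfo)")
  TRUE
})

#' Construct a SignalTrack from tag positions
#'
#' @param positions `GRanges` of tag positions (wider ranges are reduced
#'   to their start coordinate).
#' @param weight per-tag weights (recycled); default 1.
#' @param layout `Seqinfo` with chromosome lengths (required unless
#'   `positions` already carries them).
#' @return A `SignalTrack`.
#' @export
SignalTrack <- function(positions, weight = 1, layout = NULL) {
  pos <- GRanges(seqnames(positions), IRanges(start(positions), width = 1L))
  if (!is.null(layout)) seqinfo(pos) <- layout[seqlevels(pos)]
  else seqinfo(pos) <- seqinfo(positions)[seqlevels(pos)]
  mcols(pos)$weight <- as.numeric(rep_len(weight, length(pos)))
  new("SignalTrack", tags = pos)
}

#' @describeIn SignalTrack total (weighted) tag count.
#' @param x a `SignalTrack`.
#' @export
tagCount <- function(x) sum(mcols(x@tags)$weight)

#' @describeIn SignalTrack tag positions as a width-1 `GRanges`.
#' @export
tagPositions <- function(x) x@tags

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack:", length(object@tags), "positions,",
      format(tagCount(object), big.mark = ","), "total tags on",
      length(seqlevels(object@tags)), "chromosome(s)\n")
})

#' MetaProfile: windowed fold-enrichment profile around aligned loci
#'
#' @slot mark signal name.
#' @slot window window size in bp.
#' @slot span total profiled span in bp (`span/window` windows).
#' @slot fold per-window fold enrichment over the genome-average count
#'   per window.
#' @slot nFeatures number of features contributing to each window
#'   (features whose window falls off a chromosome end are dropped from
#'   that window's average).
#' @export
setClass("MetaProfile",
  representation(mark = "character", window = "integer", span = "integer",
                 fold = "numeric", nFeatures = "integer"))

setValidity("MetaProfile", function(object) {
  nw <- object@span %/% object@window
  if (length(object@fold) != nw) return("number of windows must equal span/window")
  if (any(object@fold < 0, na.rm = TRUE)) return("fold values must be >= 0")
  TRUE
})

#' @describeIn MetaProfile per-window fold-enrichment values.
#' @param x a `MetaProfile`.
#' @export
foldEnrichment <- function(x) x@fold

#' @describeIn MetaProfile window midpoint offsets (bp) relative to the
#'   feature anchor.
#' @export
windowOffsets <- function(x) {
  nw <- x@span %/% x@window
  as.integer(seq_len(nw) - 1L) * x@window - x@span %/% 2L + x@window %/% 2L
}

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile [", object@mark, "]: ", length(object@fold),
      " x ", object@window, " bp windows over ", object@span, " bp; ",
      "central fold = ", round(object@fold[length(object@fold) %/% 2L], 3),
      "\n", sep = "")
})

#' CongruenceScore: slope-weighted rank agreement of two profiles
#'
#' @slot rho Spearman rank correlation of paired window values.
#' @slot slope least-squares slope of the test profile regressed on the
#'   canonical profile.
#' @slot score `rho * abs(slope)` (the correlation carries the sign);
#'   values above 1 indicate a congruent profile with
#'   stronger-than-canonical enrichment.
#' @export
setClass("CongruenceScore",
  representation(rho = "numeric", slope = "numeric", score = "numeric"))

setValidity("CongruenceScore", function(object) {
  if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-12)
    return("rho must lie in [-1, 1]")
  TRUE
})

setMethod("show", "CongruenceScore", function(object) {
  cat(sprintf("CongruenceScore: rho = %.4f, slope = %.4f, score = %.4f\n",
              object@rho, object@slope, object@score))
})

#' EnrichmentReport: observed vs expected count with a one-cell chi-square
#'
#' @slot observed observed count.
#' @slot expected expected count under the null.
#' @slot statistic `(observed - expected)^2 / expected`.
#' @slot pValue upper tail of the chi-square distribution with 1 df.
#' @slot method how the expectation was obtained (`"analytic"` or
#'   `"simulated"`).
#' @export
setClass("EnrichmentReport",
  representation(observed = "numeric", expected = "numeric",
                 statistic = "numeric", pValue = "numeric",
                 method = "character"))

setValidity("EnrichmentReport", function(object) {
  if (object@statistic < 0) return("chi-square statistic must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) return("p must lie in [0, 1]")
  TRUE
})

setMethod("show", "EnrichmentReport", function(object) {
  cat(sprintf(
    "EnrichmentReport (%s): observed = %s, expected = %s, chi^2 = %.1f, p = %.3g\n",
    object@method, format(object@observed, big.mark = ","),
    format(round(object@expected, 1), big.mark = ","),
    object@statistic, object@pValue))
})

#' @describeIn EnrichmentReport the chi-square statistic.
#' @param x object to extract from.
#' @export
chiSquare <- function(x) x@statistic

#' @describeIn EnrichmentReport the upper-tail p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setMethod("pValue", "EnrichmentReport", function(x) x@pValue)

#' MotifNullResult: observed motif count against a resampled null
#'
#' @slot motifId motif identifier.
#' @slot observed total motif hits in the target sequences.
#' @slot nullCounts motif hit totals in each resampled null replicate.
#' @slot nullMedian median of the null distribution (the empirical
#'   expectation).
#' @slot nullSD sample standard deviation of the null distribution.
#' @slot zScore `(observed - nullMedian) / nullSD` (NA when degenerate).
#' @slot pValue one-sided normal upper-tail p (NA when degenerate).
#' @slot degenerate TRUE when the null distribution has zero spread.
#' @export
setClass("MotifNullResult",
  representation(motifId = "character", observed = "numeric",
                 nullCounts = "numeric", nullMedian = "numeric",
                 nullSD = "numeric", zScore = "numeric", pValue = "numeric",
                 degenerate = "logical"))

setValidity("MotifNullResult", function(object) {
  if (!length(object@nullCounts)) return("null distribution is empty")
  if (!is.na(object@nullSD) && object@nullSD < 0) return("negative null SD")
  TRUE
})

setMethod("show", "MotifNullResult", function(object) {
  cat(sprintf(
    "MotifNullResult [%s]: observed = %d, null median = %.1f, sd = %.2f",
    object@motifId, object@observed, object@nullMedian, object@nullSD))
  if (object@degenerate) cat(" (degenerate null: no Z/p)\n")
  else cat(sprintf(", Z = %.2f, p = %.3g\n", object@zScore, object@pValue))
})

#' @export
setMethod("pValue", "MotifNullResult", function(x) x@pValue)

#' @describeIn MotifNullResult the Z score against the resampled null.
#' @param x a `MotifNullResult`.
#' @export
zScore <- function(x) x@zScore

#' BinnedRegression: binned density-vs-response regression
#'
#' @slot nBins number of equal-count bins.
#' @slot binDensity per-bin mean density.
#' @slot binResponse per-bin mean response.
#' @slot r Pearson correlation across the bin pairs (NA when degenerate).
#' @slot pValue two-sided p for the correlation.
#' @export
setClass("BinnedRegression",
  representation(nBins = "integer", binDensity = "numeric",
                 binResponse = "numeric", r = "numeric", pValue = "numeric"))

setValidity("BinnedRegression", function(object) {
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12) return("|r| must be <= 1")
  if (length(object@binDensity) != object@nBins) return("bin count mismatch")
  TRUE
})

setMethod("show", "BinnedRegression", function(object) {
  cat(sprintf("BinnedRegression: %d bins, r = %.3f, p = %.3g\n",
              object@nBins, object@r, object@pValue))
})

#' @export
setMethod("pValue", "BinnedRegression", function(x) x@pValue)

#' HypergeomResult: upper-tail hypergeometric overlap test
#'
#' @slot N universe size.
#' @slot K gene-set size within the universe.
#' @slot n number of drawn (e.g. feature-linked) genes.
#' @slot k observed overlap.
#' @slot pValue `P(X >= k)` for `X ~ Hypergeom(N, K, n)`.
#' @export
setClass("HypergeomResult",
  representation(N = "integer", K = "integer", n = "integer", k = "integer",
                 pValue = "numeric"))

setValidity("HypergeomResult", function(object) {
  if (object@k > min(object@K, object@n)) return("k must be <= min(K, n)")
  if (object@pValue < 0 || object@pValue > 1) return("p must lie in [0, 1]")
  TRUE
})

setMethod("show", "HypergeomResult", function(object) {
  cat(sprintf(
    "HypergeomResult: %d/%d drawn genes in a set of %d (universe %d), p = %.3g\n",
    object@k, object@n, object@K, object@N, object@pValue))
})

#' @export
setMethod("pValue", "HypergeomResult", function(x) x@pValue)

#' PWMotif: position probability matrix motif
#'
#' @slot id motif identifier.
#' @slot matrix 4 x L probability matrix, rows A, C, G, T; each column
#'   sums to 1.
#' @slot pseudocount pseudocount added to probabilities before the
#'   log-odds transform.
#' @export
setClass("PWMotif",
  representation(id = "character", matrix = "matrix", pseudocount = "numeric"))

setValidity("PWMotif", function(object) {
  m <- object@matrix
  if (nrow(m) != 4L) return("matrix must have 4 rows (A, C, G, T)")
  if (any(abs(colSums(m) - 1) > 1e-9)) return("each position must sum to 1")
  if (any(m < 0)) return("negative probabilities")
  if (object@pseudocount <= 0) return("pseudocount must be positive")
  TRUE
})

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif [", object@id, "]: length ", ncol(object@matrix),
      ", consensus ", pwmConsensus(object), "\n", sep = "")
})

#' RegexMotif: IUPAC-degenerate sequence motif
#'
#' @slot id motif identifier.
#' @slot pattern IUPAC nucleotide pattern (e.g. `"TGASTCA"`).
#' @export
setClass("RegexMotif", representation(id = "character", pattern = "character"))

setValidity("RegexMotif", function(object) {
  pat <- toupper(object@pattern)
  if (!nzchar(pat)) return("empty pattern")
  ok <- strsplit(pat, "")[[1L]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok)) return(paste0("invalid IUPAC code: ",
                              substr(pat, which(!ok)[1L], which(!ok)[1L])))
  TRUE
})

#' Construct a RegexMotif
#' @param id motif identifier.
#' @param pattern IUPAC nucleotide pattern.
#' @return A `RegexMotif`.
#' @export
RegexMotif <- function(id, pattern) {
  new("RegexMotif", id = as.character(id), pattern = toupper(pattern))
}

setMethod("show", "RegexMotif", function(object) {
  cat("RegexMotif [", object@id, "]: ", object@pattern, "\n", sep = "")
})
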