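# Weighted tag count per query range (tags assigned by start position).
weightedTagCounts <- function(queries, track) {
  tags <- tagPositions(track)
  hits <- findOverlaps(queries, tags, ignore.strand = TRUE)
  out <- numeric(length(queries))
  if (length(hits)) {
    agg <- rowsum(mcols(tags)$weight[subjectHits(hits)], queryHits(hits))
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Windowed fold-enrichment metaprofile around aligned features
#'
#' Tag counts are aggregated in fixed-size windows tiling a span
#' centered on each feature's midpoint, averaged across features, and
#' expressed as fold enrichment over the genome-average tag count per
#' window-size bp (total tags divided by genome length / window size).
#' Windows that fall off a chromosome end are dropped from that
#' window's average (and reported via a message).
#'
#' @param features `GRanges`; width-1 ranges are used as anchors,
#'   wider ranges are represented by their midpoints.
#' @param track a [SignalTrack].
#' @param span total profiled span in bp (default 20 kb).
#' @param window window size in bp (default 500); must divide `span`.
#' @param mark name stored in the profile.
#' @return A [MetaProfile] with `span/window` windows.
#' @export
metaprofile <- function(features, track, span = 20000L, window = 500L,
                        mark = "signal") {
  stopifnot(is(track, "SignalTrack"))
  if (length(features) == 0L) stop("no features to profile")
  span <- as.integer(span); window <- as.integer(window)
  if (span %% window != 0L) stop("window size must divide span")
  total <- tagCount(track)
  if (total <= 0) stop("empty track: fold enrichment undefined")
  nw <- span %/% window
  mid <- start(features) + (width(features) - 1L) %/% 2L

  # window j (1..nw) covers 0-based [mid0 - span/2 + (j-1)*window, ...+window)
  offsets <- (seq_len(nw) - 1L) * window - span %/% 2L
  featIdx <- rep(seq_along(features), each = nw)
  winIdx <- rep(seq_len(nw), times = length(features))
  wStart <- (mid[featIdx] - 1L) + offsets[winIdx] + 1L
  chrom <- as.character(seqnames(features))[featIdx]
  lens <- seqlengths(track@tags)[chrom]
  if (anyNA(lens))
    stop("feature chromosome absent from track layout: ",
         chrom[which(is.na(lens))[1L]])
  inBounds <- wStart >= 1L & (wStart + window - 1L) <= lens
  nDropped <- sum(!inBounds)
  if (nDropped)
    message(nDropped, " partial window(s) at chromosome edges dropped")
  if (!any(inBounds)) stop("all profile windows fall outside chromosomes")

  wins <- GRanges(chrom[inBounds],
                  IRanges(wStart[inBounds], width = window))
  counts <- weightedTagCounts(wins, track)
  sums <- tapply(counts, winIdx[inBounds], sum)
  ns <- tapply(counts, winIdx[inBounds], length)
  meanCount <- numeric(nw); nFeat <- integer(nw)
  idx <- as.integer(names(sums))
  meanCount[idx] <- sums / ns
  nFeat[idx] <- as.integer(ns)

  G <- sum(as.numeric(seqlengths(track@tags)))
  genomeAvg <- total / (G / window)
  new("MetaProfile", mark = mark, window = window, span = span,
      fold = meanCount / genomeAvg, nFeatures = nFeat)
}

#' Slope-weighted rank congruence of two metaprofiles
#'
#' Spearman rank correlation of the paired per-window values, weighted
#' by the magnitude of the ordinary least-squares slope of the test
#' profile regressed on the canonical profile (`score = rho * |slope|`,
#' so the correlation alone carries the sign). A score of 1 means
#' identical shape and magnitude; scores above 1 indicate a congruent
#' profile with stronger-than-canonical enrichment; negative scores
#' indicate anti-correlated profiles.
#'
#' @param canonical reference profile ([MetaProfile] or numeric vector).
#' @param test test profile of the same number of windows.
#' @return A [CongruenceScore].
#' @export
congruence <- function(canonical, test) {
  a <- if (is(canonical, "MetaProfile")) foldEnrichment(canonical) else as.numeric(canonical)
  b <- if (is(test, "MetaProfile")) foldEnrichment(test) else as.numeric(test)
  if (length(a) != length(b)) stop("profiles must have equal window counts")
  if (length(a) < 3L) stop("too few windows for a congruence score")
  if (var(a) == 0 || var(b) == 0)
    stop("zero variance in a profile: congruence undefined")
  rho <- cor(a, b, method = "spearman")
  slope <- cov(a, b) / var(a)
  new("CongruenceScore", rho = rho, slope = slope,
      score = rho * abs(slope))
}

#' Rank chromatin marks by profile congruence
#'
#' Computes the slope-weighted rank congruence between the canonical and
#' test profile of each mark and orders marks by descending score,
#' establishing the relative order of mark enrichment congruence.
#'
#' @param canonicalProfiles named list of [MetaProfile]s (or numeric
#'   vectors), one per mark.
#' @param testProfiles named list with the same mark names.
#' @return A `data.frame` with columns `mark`, `rho`, `slope`, `score`,
#'   sorted by descending score.
#' @export
rankMarks <- function(canonicalProfiles, testProfiles) {
  cn <- names(canonicalProfiles); tn <- names(testProfiles)
  if (is.null(cn) || is.null(tn) || !setequal(cn, tn) ||
      length(cn) != length(tn))
    stop("canonical and test profiles must cover the same mark names")
  scores <- lapply(cn, function(m)
    congruence(canonicalProfiles[[m]], testProfiles[[m]]))
  df <- data.frame(mark = cn,
                   rho = vapply(scores, function(s) s@rho, numeric(1L)),
                   slope = vapply(scores, function(s) s@slope, numeric(1L)),
                   score = vapply(scores, function(s) s@score, numeric(1L)))
  df[order(-df$score), , drop = FALSE]
}

#' Tag-density fold enrichment of a target set over a reference set
#'
#' Weighted tag count per merged basepair in the target intervals
#' divided by the same density in the reference intervals (e.g. TF
#' occupancy of enhancer-associated repeats relative to non-enhancer
#' repeats).
#'
#' @param target non-empty `GRanges`.
#' @param reference non-empty `GRanges`.
#' @param track a [SignalTrack].
#' @return Fold enrichment (positive number).
#' @export
occupancyEnrichment <- function(target, reference, track) {
  stopifnot(is(track, "SignalTrack"))
  if (length(target) == 0L || length(reference) == 0L)
    stop("target and reference must be non-empty")
  if (tagCount(track) <= 0) stop("empty track")
  dens <- function(set) {
    m <- mergeIntervals(set)
    sum(weightedTagCounts(m, track)) / sum(as.numeric(width(m)))
  }
  dRef <- dens(reference)
  if (dRef == 0) stop("zero tag density in reference set")
  dens(target) / dRef
}
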