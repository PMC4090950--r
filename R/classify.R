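#' Classify repeats relative to enhancer anchors and spans
#'
#' A repeat containing one or more enhancer anchor basepairs provides an
#' enhancer core and is labelled `MIR_ENHANCER`; otherwise a repeat with
#' at least 1 bp of overlap with any enhancer span is enhancer-linked
#' (`ENHANCER_MIR`); all remaining repeats are `NON_ENHANCER_MIR`. The
#' three labels are mutually exclusive and exhaustive. Anchor
#' containment is half-open: an anchor at 0-based offset `a` lies in a
#' repeat `[s, e)` iff `s <= a < e`.
#'
#' @param enhancers an [EnhancerSet].
#' @param repeats `GRanges` of repeat annotations; `names(repeats)` (or
#'   a `name`/`id` metadata column) provide stable identifiers.
#' @return The repeats `GRanges` with metadata columns `id`, `label`
#'   (factor with the three levels above) and `linkedEnhancers`
#'   (`CharacterList` of enhancer ids whose anchor or span justified the
#'   label).
#' @export
classifyRepeats <- function(enhancers, repeats) {
  stopifnot(is(enhancers, "EnhancerSet"), is(repeats, "GRanges"))
  ids <- repeatIds(repeats)
  if (anyDuplicated(ids)) stop("repeat ids must be unique")
  a <- anchors(enhancers)
  spans <- suppressMessages(enhancerSpans(enhancers))
  eids <- names(a)

  hitA <- findOverlaps(repeats, a, ignore.strand = TRUE)
  hitS <- findOverlaps(repeats, spans, ignore.strand = TRUE)
  isCore <- countQueryHits(hitA) > 0L
  isLinked <- !isCore & countQueryHits(hitS) > 0L

  label <- factor(rep("NON_ENHANCER_MIR", length(repeats)),
                  levels = c("MIR_ENHANCER", "ENHANCER_MIR",
                             "NON_ENHANCER_MIR"))
  label[isCore] <- "MIR_ENHANCER"
  label[isLinked] <- "ENHANCER_MIR"

  linked <- rep(CharacterList(character(0)), length(repeats))
  if (length(hitA))
    linked[unique(queryHits(hitA))] <-
      unname(splitAsList(eids[subjectHits(hitA)], queryHits(hitA)))
  li <- which(isLinked)
  if (length(hitS)) {
    hs <- hitS[queryHits(hitS) %in% li]
    if (length(hs))
      linked[unique(queryHits(hs))] <-
        unname(splitAsList(eids[subjectHits(hs)], queryHits(hs)))
  }

  out <- repeats
  mcols(out)$id <- ids
  mcols(out)$label <- label
  mcols(out)$linkedEnhancers <- linked
  out
}

repeatIds <- function(repeats) {
  ids <- names(repeats)
  if (is.null(ids)) ids <- mcols(repeats)$id
  if (is.null(ids)) ids <- mcols(repeats)$name
  if (is.null(ids)) ids <- sprintf("rep%06d", seq_along(repeats))
  as.character(ids)
}

#' Count enhancers whose span is overlapped by at least one repeat
#'
#' The per-enhancer counterpart of [classifyRepeats()]: an enhancer with
#' several linked repeats counts once.
#'
#' @inheritParams classifyRepeats
#' @return Integer count of enhancers with >= 1 bp repeat overlap in
#'   their span.
#' @export
enhancersWithRepeats <- function(enhancers, repeats) {
  spans <- suppressMessages(enhancerSpans(enhancers))
  sum(countOverlaps(spans, repeats, ignore.strand = TRUE) > 0L)
}

#' Analytic expected number of repeat-provided enhancer cores
#'
#' Under a null of anchors falling uniformly at random, each repeat of
#' length `L` contains an anchor with probability `~ nEnhancers * L /
#' genomeLength`, so the expected number of anchor-containing repeats is
#' the genome-wide enhancer density (enhancers per bp) multiplied by the
#' total repeat length in bp. Repeat lengths are summed as annotated
#' (not merged), matching the per-repeat counting of
#' [classifyRepeats()].
#'
#' @inheritParams classifyRepeats
#' @param layout `Seqinfo` with chromosome lengths.
#' @return Expected count (float).
#' @export
expectedCoreCount <- function(enhancers, repeats, layout) {
  G <- sum(as.numeric(seqlengths(layout)))
  if (!isTRUE(G > 0)) stop("genome layout has zero total length")
  if (length(repeats) == 0L) return(0)
  bad <- which(width(repeats) < 1L)
  if (length(bad))
    stop("malformed interval (start >= end): ",
         as.character(repeats[bad[1L]]))
  length(enhancers) / G * sum(as.numeric(width(repeats)))
}

#' Analytic expected number of repeats overlapping any enhancer span
#'
#' Under uniform placement, a repeat of length `L` overlaps a merged
#' span block of `S_c` bp comprising `m_c` disjoint intervals on a
#' chromosome with probability `(S_c + m_c (L - 1)) / G` summed over
#' chromosomes (`G` = genome length; boundary effects at chromosome
#' ends are neglected). The expectation is the sum over repeats,
#' clipped at 1 per repeat.
#'
#' @inheritParams expectedCoreCount
#' @return Expected count of enhancer-associated repeats under uniform
#'   placement.
#' @export
expectedLinkedRepeats <- function(enhancers, repeats, layout) {
  G <- sum(as.numeric(seqlengths(layout)))
  if (!isTRUE(G > 0)) stop("genome layout has zero total length")
  if (length(repeats) == 0L) return(0)
  spans <- reduce(suppressMessages(enhancerSpans(enhancers)),
                  ignore.strand = TRUE)
  S <- sum(as.numeric(width(spans)))
  M <- length(spans)
  sum(pmin(1, (S + M * (as.numeric(width(repeats)) - 1)) / G))
}

#' Simulated expected number of enhancers overlapped by random repeats
#'
#' Places random genomic sites matching the repeat set in number and
#' length (uniformly per chromosome, weighted by chromosome length,
#' sites free to overlap each other) and counts the enhancers whose span
#' is overlapped by at least one site; the mean over replicates is the
#' simulated expectation.
#'
#' @inheritParams expectedCoreCount
#' @param nReps number of randomization replicates (default 1000).
#' @param seed integer seed.
#' @return Mean overlapped-enhancer count over replicates, with the
#'   per-replicate counts in attribute `"replicates"`.
#' @export
expectedEnhancersWithRepeats <- function(enhancers, repeats, layout,
                                         nReps = 1000L, seed = NULL) {
  stopifnot(nReps >= 1L)
  if (length(repeats) == 0L)
    return(structure(0, replicates = numeric(nReps)))
  spans <- suppressMessages(enhancerSpans(enhancers))
  lens <- seqlengths(layout)
  L <- width(repeats)
  if (any(L > max(lens)))
    stop("repeat longer than every chromosome: cannot place random sites")
  n <- length(L)
  withSeed(seed, {
    # all replicates placed in one batch: site start uniform on
    # [0, chromLen - L], chromosome weighted by length among those long
    # enough for the site
    Lall <- rep.int(L, nReps)
    total <- n * nReps
    chromIdx <- if (all(lens >= max(L))) {
      sample.int(length(lens), total, replace = TRUE,
                 prob = as.numeric(lens))
    } else {
      vapply(Lall, function(l) {
        ok <- which(lens >= l)
        if (length(ok) == 1L) ok else sample(ok, 1L,
                                             prob = as.numeric(lens[ok]))
      }, integer(1L))
    }
    maxStart <- lens[chromIdx] - Lall + 1L
    starts <- pmin(floor(runif(total, min = 1, max = maxStart + 1)),
                   maxStart)
    sites <- GRanges(names(lens)[chromIdx],
                     IRanges(as.integer(starts), width = Lall))
    repIdx <- rep(seq_len(nReps), each = n)
    hits <- findOverlaps(sites, spans, ignore.strand = TRUE)
    counts <- numeric(nReps)
    if (length(hits)) {
      pair <- unique(cbind(repIdx[queryHits(hits)], subjectHits(hits)))
      tab <- tabulate(pair[, 1L], nbins = nReps)
      counts <- as.numeric(tab)
    }
    structure(mean(counts), replicates = counts)
  })
}

#' One-cell chi-square test of an observed count against its expectation
#'
#' The statistic is `(observed - expected)^2 / expected`, referred to
#' the chi-square distribution with one degree of freedom (upper tail).
#'
#' @param observed observed count.
#' @param expected expected count (> 0).
#' @param method label recording how the expectation was derived.
#' @return An [EnrichmentReport].
#' @export
#' @examples
#' chiSquare(oneCellChiSq(934, 669))  # ~105
oneCellChiSq <- function(observed, expected,
                         method = c("analytic", "simulated")) {
  method <- match.arg(method)
  if (!isTRUE(expected > 0)) stop("expected count must be > 0")
  stat <- (observed - expected)^2 / expected
  new("EnrichmentReport", observed = as.numeric(observed),
      expected = as.numeric(expected), statistic = stat,
      pValue = pchisq(stat, df = 1L, lower.tail = FALSE),
      method = method)
}
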