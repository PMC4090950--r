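#' Cell-type-specific features by coordinate difference
#'
#' Features of one condition absent (by exact `chrom:start-end`
#' coordinate key) from a second condition — e.g. enhancer-associated
#' repeats present in one cell line and absent in another.
#'
#' @param setA `GRanges` of features in the condition of interest.
#' @param setB `GRanges` of features in the comparison condition.
#' @return The subset of `setA` whose coordinates do not occur in
#'   `setB`.
#' @export
cellSpecificFeatures <- function(setA, setB) {
  key <- function(gr) paste0(seqnames(gr), ":", start(gr), "-", end(gr))
  setA[!key(setA) %in% key(setB)]
}

#' Link genes to nearby features
#'
#' A gene is linked when its anchor interval lies within `maxDistance`
#' bp (edge-to-edge; overlap counts as distance 0) of at least one
#' feature. The result is invariant to feature order and duplication.
#'
#' @param features `GRanges` of features.
#' @param genes `GRanges` of genes with identifiers in `names()` or an
#'   `id`/`name` metadata column.
#' @param maxDistance linking distance in bp (default 100 kb).
#' @param anchor `"body"` (whole gene interval, default) or `"tss"`
#'   (strand-aware transcription start position).
#' @return Character vector of linked gene ids (unique, in gene order).
#' @export
linkGenes <- function(features, genes, maxDistance = 100000L,
                      anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  ids <- repeatIds(genes)
  target <- if (anchor == "tss") resize(genes, width = 1L, fix = "start")
            else genes
  hit <- overlapsAny(target, features, maxgap = as.integer(maxDistance),
                     ignore.strand = TRUE)
  unique(ids[hit])
}

#' Upper-tail hypergeometric overlap test
#'
#' For a universe of `N` genes of which `K` belong to a gene set, and
#' `n` drawn (e.g. feature-linked) genes of which `k` fall in the set,
#' computes `P(X >= k)` for `X ~ Hypergeom(N, K, n)` (the upper tail
#' includes the observed overlap). The tail is evaluated in log space
#' via [stats::phyper()].
#'
#' @param N universe size.
#' @param K gene-set size.
#' @param n number of drawn genes.
#' @param k observed overlap.
#' @return A [HypergeomResult].
#' @export
#' @examples
#' pValue(hypergeomTest(10, 5, 4, 4))  # 5/210
hypergeomTest <- function(N, K, n, k) {
  N <- as.integer(N); K <- as.integer(K)
  n <- as.integer(n); k <- as.integer(k)
  if (K > N || n > N) stop("set and draw sizes must not exceed the universe")
  if (k > min(K, n) || k < 0L) stop("inconsistent overlap count k")
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  new("HypergeomResult", N = N, K = K, n = n, k = k, pValue = p)
}

#' Gene-set enrichment of a linked gene list
#'
#' Tests each gene set for over-representation among the linked genes
#' with the upper-tail hypergeometric test, restricted to the supplied
#' universe, and adjusts across sets by Benjamini-Hochberg.
#'
#' @param linkedGenes character vector of linked gene ids.
#' @param geneSets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param universe character vector of all gene ids under study; the
#'   universe size is a configuration choice, defaulting to the supplied
#'   gene model.
#' @return `data.frame` with per-set columns `set`, `N`, `K`, `n`, `k`,
#'   `p` and BH-adjusted `q`, ordered by `p`.
#' @export
genesetEnrichment <- function(linkedGenes, geneSets, universe) {
  universe <- unique(universe)
  drawn <- intersect(linkedGenes, universe)
  rows <- lapply(names(geneSets), function(s) {
    members <- intersect(geneSets[[s]], universe)
    k <- length(intersect(drawn, members))
    res <- hypergeomTest(length(universe), length(members),
                         length(drawn), k)
    data.frame(set = s, N = res@N, K = res@K, n = res@n, k = res@k,
               p = res@pValue)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
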