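#' Tissue-specificity index
#'
#' For a gene with intensities across `N >= 2` tissues, the index is
#' `TS = sum(1 - x_i) / (N - 1)` where `x_i` is the intensity in tissue
#' `i` divided by the gene's maximum intensity. TS is 0 for perfectly
#' uniform expression and 1 for single-tissue expression, and is
#' invariant to rescaling the profile.
#'
#' @param values numeric vector of per-tissue intensities, or a
#'   genes-by-tissues matrix (one index per row).
#' @return TS in `[0, 1]`; genes with all-zero profiles are flagged
#'   with a warning and return `NA`.
#' @export
#' @examples
#' tsIndex(c(10, 5, 5))  # 0.5
tsIndex <- function(values) {
  if (is.matrix(values)) return(apply(values, 1L, tsIndex))
  if (length(values) < 2L) stop("TS requires >= 2 tissues")
  if (any(values < 0)) stop("negative intensity")
  mx <- max(values)
  if (mx == 0) {
    warning("all-zero expression profile: TS undefined")
    return(NA_real_)
  }
  sum(1 - values / mx) / (length(values) - 1L)
}

#' Shannon-entropy tissue specificity
#'
#' Entropy (bits) of the across-tissue expression distribution
#' `p_i = value_i / sum(values)`. Low entropy indicates tissue-specific
#' expression; the maximum, `log2(N)`, indicates uniform expression.
#'
#' @inheritParams tsIndex
#' @return Entropy in bits; all-zero profiles are flagged with a
#'   warning and return `NA`.
#' @export
#' @examples
#' entropySpecificity(c(1, 1, 1, 1))  # 2 bits
entropySpecificity <- function(values) {
  if (is.matrix(values)) return(apply(values, 1L, entropySpecificity))
  if (any(values < 0)) stop("negative intensity")
  tot <- sum(values)
  if (tot == 0) {
    warning("all-zero expression profile: entropy undefined")
    return(NA_real_)
  }
  p <- values / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Feature density in and around genes
#'
#' For each gene, counts the features with >= 1 bp overlap of the gene
#' body extended by `flank` bp on each side (clipped at chromosome
#' ends), and divides by the extended interval's length in bp.
#'
#' @param genes `GRanges` of gene bodies (chromosome lengths required
#'   for clipping).
#' @param features `GRanges` of features (e.g. enhancer-associated
#'   repeats).
#' @param flank bp added on each side of the gene body (default 10 kb).
#' @return The `genes` `GRanges` with metadata columns `featureCount`,
#'   `flankWidth` and `density` (features per bp).
#' @export
geneFeatureDensity <- function(genes, features, flank = 10000L) {
  stopifnot(is(genes, "GRanges"), is(features, "GRanges"))
  flanked <- suppressWarnings(trim(genes + as.integer(flank)))
  flanked <- restrict(flanked, start = 1L)
  cnt <- countOverlaps(flanked, features, ignore.strand = TRUE)
  out <- genes
  mcols(out)$featureCount <- cnt
  mcols(out)$flankWidth <- width(flanked)
  mcols(out)$density <- cnt / width(flanked)
  out
}

#' Binned regression of feature density against an expression response
#'
#' Genes are sorted by density (stable order for ties), split into
#' `nBins` equal-count bins, and the per-bin mean density is correlated
#' (Pearson, two-sided) with the per-bin mean response. The response
#' may be an expression level, a TS index, or an entropy — the
#' regression is agnostic.
#'
#' @param densities per-gene densities.
#' @param responses per-gene responses (same length; `NA` genes are
#'   dropped).
#' @param nBins number of equal-count bins (default 100); must not
#'   exceed the number of genes with defined responses.
#' @return A [BinnedRegression].
#' @export
binnedRegression <- function(densities, responses, nBins = 100L) {
  if (length(densities) != length(responses))
    stop("densities and responses must have equal length")
  keep <- !is.na(responses) & !is.na(densities)
  d <- densities[keep]; y <- responses[keep]
  nBins <- as.integer(nBins)
  if (length(d) < nBins)
    stop("fewer genes (", length(d), ") than bins (", nBins,
         "): reduce nBins")
  ord <- order(d)  # stable for ties
  bin <- ceiling(seq_along(ord) * nBins / length(ord))
  bd <- as.numeric(tapply(d[ord], bin, mean))
  by <- as.numeric(tapply(y[ord], bin, mean))
  if (sd(by) == 0 || sd(bd) == 0) {
    warning("constant bin means: correlation undefined")
    return(new("BinnedRegression", nBins = nBins, binDensity = bd,
               binResponse = by, r = NA_real_, pValue = NA_real_))
  }
  ct <- cor.test(bd, by, method = "pearson")
  new("BinnedRegression", nBins = nBins, binDensity = bd,
      binResponse = by, r = unname(ct$estimate), pValue = ct$p.value)
}
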