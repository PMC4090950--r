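# Independent brute-force oracles used across the suite. These work on
# per-basepair boolean arrays or exhaustive enumeration and share no code
# with the package implementations they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# per-base occupancy: fraction of region basepairs covered by features,
# computed on logical vectors (one chromosome, 0-based half-open input)
occupancyOracle <- function(regions0, features0, chromLen) {
  inRegion <- logical(chromLen)
  for (r in regions0) inRegion[(r[1] + 1):r[2]] <- TRUE
  inFeature <- logical(chromLen)
  for (f in features0) inFeature[(f[1] + 1):f[2]] <- TRUE
  sum(inRegion & inFeature) / sum(inRegion)
}

# union-of-basepairs merge on a boolean array -> 0-based intervals
mergeOracle <- function(intervals0, chromLen) {
  covered <- logical(chromLen)
  for (iv in intervals0) covered[(iv[1] + 1):iv[2]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values], ends[r$values])
}

IUPAC_SETS <- lapply(Biostrings::IUPAC_CODE_MAP, function(x)
  strsplit(x, "")[[1]])

# does IUPAC pattern match seq at 1-based offset? subject letters are
# literal (N in subject only matches a pattern N)
iupacMatchesAt <- function(seqChars, patChars, at) {
  for (j in seq_along(patChars)) {
    s <- seqChars[at + j - 1]
    if (!s %in% IUPAC_SETS[[patChars[j]]]) return(FALSE)
  }
  TRUE
}

revCompPattern <- function(pattern) {
  as.character(reverseComplement(DNAString(pattern)))
}

# both-strand hit count by full enumeration of windows
regexOracle <- function(sequence, pattern) {
  sc <- strsplit(sequence, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  rc <- strsplit(revCompPattern(pattern), "")[[1]]
  n <- length(sc) - length(pc) + 1
  if (n < 1) return(0L)
  hits <- 0L
  for (i in seq_len(n))
    if (iupacMatchesAt(sc, pc, i) || iupacMatchesAt(sc, rc, i))
      hits <- hits + 1L
  hits
}

# upper-tail hypergeometric by direct summation of binomial coefficients
hyperOracle <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small two-chromosome layout used by several tests
toyLayout <- function(len1 = 1e6, len2 = 8e5)
  GenomeInfoDb::Seqinfo(seqnames = c("chrA", "chrB"),
                        seqlengths = c(len1, len2))
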