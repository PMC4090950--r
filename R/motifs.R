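#' Construct a PWMotif from a probability or count matrix
#'
#' @param id motif identifier.
#' @param m a 4 x L (rows A, C, G, T) or L x 4 matrix of per-position
#'   base probabilities or counts; counts are column-normalized.
#' @param pseudocount pseudocount added before the log-odds transform
#'   (default 0.01).
#' @return A [PWMotif].
#' @export
#' @examples
#' # degenerate motif matching exactly "AAAA"
#' pwMotif("allA", matrix(c(1, 0, 0, 0), nrow = 4, ncol = 4))
pwMotif <- function(id, m, pseudocount = 0.01) {
  m <- as.matrix(m)
  if (nrow(m) != 4L && ncol(m) == 4L) m <- t(m)
  if (nrow(m) != 4L) stop("matrix must have 4 rows or 4 columns (A, C, G, T)")
  if (!is.null(rownames(m))) {
    if (!setequal(toupper(rownames(m)), c("A", "C", "G", "T")))
      stop("matrix rows must be named A, C, G, T")
    m <- m[match(c("A", "C", "G", "T"), toupper(rownames(m))), , drop = FALSE]
  }
  cs <- colSums(m)
  if (any(cs <= 0)) stop("position with zero total count")
  m <- sweep(m, 2L, cs, "/")
  rownames(m) <- c("A", "C", "G", "T")
  new("PWMotif", id = as.character(id), matrix = m,
      pseudocount = pseudocount)
}

#' @describeIn pwMotif consensus string (most probable base per position).
#' @param pwm a `PWMotif`.
#' @export
pwmConsensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm@matrix, 2L, which.max)],
        collapse = "")
}

# Log-odds score matrix vs a uniform 0.25 background, with pseudocount
# applied to both numerator and background so a background-probability
# base (and any N) contributes 0.
logOddsMatrix <- function(pwm) {
  log2((pwm@matrix + pwm@pseudocount) / (0.25 + pwm@pseudocount))
}

reverseComplementPwm <- function(pwm) {
  m <- pwm@matrix[4:1, rev(seq_len(ncol(pwm@matrix))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  new("PWMotif", id = pwm@id, matrix = m, pseudocount = pwm@pseudocount)
}

encodeDna <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1L]]
  code <- match(chars, c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L  # N and other ambiguity codes score as background
  code
}

pwmPositionScores <- function(code, lo) {
  L <- ncol(lo); n <- length(code)
  if (n < L) return(numeric(0L))
  s <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    lookup <- c(0, lo[, j])  # index 1 = ambiguous base, contributes 0
    s <- s + lookup[code[j:(j + n - L)] + 1L]
  }
  s
}

#' Count PWM motif hits in a sequence
#'
#' Scores every position of the sequence (and its reverse complement,
#' via the reverse-complemented matrix applied to the forward strand)
#' with the log-odds of the PWM against a uniform 0.25 background. A
#' position is a hit when either strand's score reaches
#' `thresholdFrac` times the maximum achievable score; strand-duplicate
#' hits at the same start position (palindromic motifs) count once.
#'
#' @param sequence a DNA string (character or `DNAString`) over
#'   A, C, G, T, N.
#' @param pwm a [PWMotif].
#' @param thresholdFrac hit threshold as a fraction of the maximum
#'   achievable log-odds score (default 0.8).
#' @return Integer hit count.
#' @export
scanPwm <- function(sequence, pwm, thresholdFrac = 0.8) {
  stopifnot(is(pwm, "PWMotif"))
  code <- encodeDna(sequence)
  lo <- logOddsMatrix(pwm)
  maxScore <- sum(apply(lo, 2L, max))
  thr <- thresholdFrac * maxScore - 1e-9
  fwd <- pwmPositionScores(code, lo)
  if (!length(fwd)) return(0L)
  rev <- pwmPositionScores(code, logOddsMatrix(reverseComplementPwm(pwm)))
  sum(fwd >= thr | rev >= thr)
}

#' Count IUPAC-degenerate motif hits in a sequence
#'
#' Matches the pattern (IUPAC ambiguity codes expanded) against the
#' forward strand, and its reverse complement likewise against the
#' forward strand; the hit count is the number of distinct match start
#' positions, so a palindromic motif is counted once per site.
#'
#' @param sequence a DNA string (character or `DNAString`).
#' @param motif a [RegexMotif] (or bare IUPAC pattern string).
#' @return Integer hit count.
#' @export
#' @examples
#' scanRegex("TGACTCAAA", RegexMotif("ap1", "TGASTCA"))
scanRegex <- function(sequence, motif) {
  if (is.character(motif)) motif <- RegexMotif(motif, motif)
  stopifnot(is(motif, "RegexMotif"))
  subject <- if (is(sequence, "DNAString")) sequence else {
    s <- toupper(as.character(sequence))
    if (!nzchar(s)) return(0L)
    DNAString(s)
  }
  pat <- DNAString(motif@pattern)
  if (length(subject) < length(pat)) return(0L)
  fwd <- start(matchPattern(pat, subject, fixed = "subject"))
  rev <- start(matchPattern(reverseComplement(pat), subject,
                            fixed = "subject"))
  length(union(fwd, rev))
}

# Can a forward-strand position ever match both the pattern and its
# reverse complement? True iff the IUPAC sets intersect at every offset.
selfCompatiblePattern <- function(pattern) {
  rc <- as.character(reverseComplement(DNAString(pattern)))
  map <- Biostrings::IUPAC_CODE_MAP
  a <- strsplit(pattern, "")[[1L]]; b <- strsplit(rc, "")[[1L]]
  all(mapply(function(x, y) {
    length(intersect(strsplit(map[[x]], "")[[1L]],
                     strsplit(map[[y]], "")[[1L]])) > 0L
  }, a, b))
}

#' Total motif hits across a sequence set
#'
#' @param seqs a `DNAStringSet` or character vector of sequences.
#' @param motif a [PWMotif] or [RegexMotif].
#' @param thresholdFrac PWM hit threshold (ignored for regex motifs).
#' @return Total hit count over all sequences.
#' @export
countMotifHits <- function(seqs, motif, thresholdFrac = 0.8) {
  if (is(motif, "PWMotif")) {
    seqs <- as.character(seqs)
    return(sum(vapply(seqs, scanPwm, integer(1L), pwm = motif,
                      thresholdFrac = thresholdFrac, USE.NAMES = FALSE)))
  }
  stopifnot(is(motif, "RegexMotif"))
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(toupper(as.character(seqs)))
  pat <- DNAString(motif@pattern)
  rc <- reverseComplement(pat)
  long <- seqs[width(seqs) >= length(pat)]
  if (!length(long)) return(0L)
  if (!selfCompatiblePattern(motif@pattern)) {
    # the two strand patterns can never share a start: plain sum
    sum(Biostrings::vcountPattern(pat, long, fixed = "subject")) +
      sum(Biostrings::vcountPattern(rc, long, fixed = "subject"))
  } else {
    f <- Biostrings::startIndex(Biostrings::vmatchPattern(pat, long, fixed = "subject"))
    r <- Biostrings::startIndex(Biostrings::vmatchPattern(rc, long, fixed = "subject"))
    sum(mapply(function(x, y) length(union(x, y)), f, r))
  }
}

motifId <- function(motif) motif@id

# Per-sequence hit counts (same counting rules as countMotifHits).
perSequenceHits <- function(seqs, motif, thresholdFrac = 0.8) {
  if (is(motif, "PWMotif"))
    return(vapply(as.character(seqs), scanPwm, integer(1L), pwm = motif,
                  thresholdFrac = thresholdFrac, USE.NAMES = FALSE))
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(toupper(as.character(seqs)))
  pat <- DNAString(motif@pattern)
  rc <- reverseComplement(pat)
  out <- integer(length(seqs))
  ok <- width(seqs) >= length(pat)
  if (!any(ok)) return(out)
  long <- seqs[ok]
  out[ok] <- if (!selfCompatiblePattern(motif@pattern)) {
    Biostrings::vcountPattern(pat, long, fixed = "subject") +
      Biostrings::vcountPattern(rc, long, fixed = "subject")
  } else {
    f <- Biostrings::startIndex(Biostrings::vmatchPattern(pat, long, fixed = "subject"))
    r <- Biostrings::startIndex(Biostrings::vmatchPattern(rc, long, fixed = "subject"))
    mapply(function(x, y) length(union(x, y)), f, r)
  }
  out
}

# Draw one null sample: sequences matched to the target lengths in
# number and length, drawn from the pool without replacement.
sampleLengthMatched <- function(poolChars, poolWidths, targetWidths) {
  available <- rep(TRUE, length(poolChars))
  out <- character(length(targetWidths))
  ord <- order(targetWidths, decreasing = TRUE)
  for (i in ord) {
    L <- targetWidths[i]
    ok <- which(available & poolWidths >= L)
    if (!length(ok))
      stop("pool exhausted: no remaining pool sequence of length >= ", L)
    pick <- if (length(ok) == 1L) ok else sample(ok, 1L)
    available[pick] <- FALSE
    maxStart <- poolWidths[pick] - L + 1L
    s <- if (maxStart == 1L) 1L else sample.int(maxStart, 1L)
    out[i] <- substr(poolChars[pick], s, s + L - 1L)
  }
  out
}

#' Empirical motif enrichment test against a resampled genomic null
#'
#' Counts motif hits in the target sequences and compares the total to
#' a null distribution obtained by repeatedly drawing, from a pool of
#' background sequences, a random sample matched to the target set in
#' number and per-sequence length (drawn without replacement within a
#' replicate, with replacement across replicates). The empirical
#' expectation is the null median; significance is a Z test with
#' `Z = (observed - median) / sd(null)` and a one-sided normal upper
#' tail. A null with zero spread is flagged degenerate and no p-value
#' is emitted.
#'
#' @param targetSeqs target sequences (`DNAStringSet` or character).
#' @param poolSeqs background pool (`DNAStringSet` or character); each
#'   target length must be coverable by some pool sequence.
#' @param motif a [PWMotif] or [RegexMotif].
#' @param nReps number of null replicates (default 1000; must be >= 2).
#' @param seed integer seed.
#' @param thresholdFrac PWM hit threshold (ignored for regex motifs).
#' @return A [MotifNullResult].
#' @export
empiricalMotifTest <- function(targetSeqs, poolSeqs, motif, nReps = 1000L,
                               seed = NULL, thresholdFrac = 0.8) {
  if (nReps < 2L) stop("nReps must be >= 2: a single replicate defines no null")
  targets <- as.character(targetSeqs)
  pool <- as.character(poolSeqs)
  if (!length(targets)) stop("empty target set")
  if (!length(pool)) stop("empty pool")
  tw <- nchar(targets); pw <- nchar(pool)
  if (length(pool) < length(targets))
    stop("pool smaller than target set: cannot draw without replacement")
  observed <- countMotifHits(targets, motif, thresholdFrac)

  # When pool and targets share a single common length, a null sample is
  # just a subset of pool sequences, so per-sequence hit counts can be
  # computed once and summed per replicate.
  uniform <- length(unique(pw)) == 1L && all(tw == pw[1L])
  withSeed(seed, {
    nullCounts <- if (uniform) {
      perPool <- perSequenceHits(pool, motif, thresholdFrac)
      vapply(seq_len(nReps), function(r)
        sum(perPool[sample.int(length(pool), length(targets))]),
        numeric(1L))
    } else {
      vapply(seq_len(nReps), function(r)
        countMotifHits(sampleLengthMatched(pool, pw, tw), motif,
                       thresholdFrac), numeric(1L))
    }
    mu <- median(nullCounts)
    sigma <- sd(nullCounts)
    degenerate <- !is.finite(sigma) || sigma == 0
    z <- if (degenerate) NA_real_ else (observed - mu) / sigma
    p <- if (degenerate) NA_real_ else pnorm(z, lower.tail = FALSE)
    new("MotifNullResult", motifId = motifId(motif),
        observed = as.numeric(observed), nullCounts = as.numeric(nullCounts),
        nullMedian = mu, nullSD = sigma, zScore = z, pValue = p,
        degenerate = degenerate)
  })
}
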