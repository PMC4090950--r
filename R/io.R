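#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param file path to the sizes file.
#' @return A [GenomeInfoDb::Seqinfo] describing the genome layout.
#' @export
readChromSizes <- function(file) {
  tab <- read.delim(file, header = FALSE, comment.char = "#",
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  if (any(duplicated(tab$chrom))) stop("duplicated chromosome name in ", file)
  if (any(tab$length <= 0L)) stop("non-positive chromosome length in ", file)
  Seqinfo(seqnames = tab$chrom, seqlengths = tab$length)
}

#' Write a chromosome-sizes table
#' @param layout a `Seqinfo`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeChromSizes <- function(layout, file) {
  write.table(data.frame(seqnames(layout), seqlengths(layout)),
              file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a BED file into a GRanges
#'
#' BED3/BED6 via [rtracklayer::import()] (track lines and `#` comments
#' are handled); coordinates are converted from the 0-based half-open
#' convention on ingestion.
#'
#' @param file path to the BED file.
#' @param layout optional `Seqinfo` to attach chromosome lengths.
#' @return A `GRanges`; BED name/score/strand columns are preserved.
#' @export
readBed <- function(file, layout = NULL) {
  gr <- rtracklayer::import(file, format = "bed")
  if (!is.null(layout)) {
    unknown <- setdiff(seqlevels(gr), seqnames(layout))
    if (length(unknown))
      stop("chromosome(s) absent from layout: ",
           paste(unknown, collapse = ", "))
    seqinfo(gr) <- layout[seqlevels(gr)]
  }
  gr
}

#' Write a GRanges to BED
#'
#' @param gr a `GRanges`; `names(gr)` or the `name` metadata column
#'   populates the BED name field.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeBed <- function(gr, file) {
  rtracklayer::export(gr, file, format = "bed")
  invisible(file)
}

#' Read enhancer anchor positions
#'
#' Accepts either a BED file of length-1 intervals at the anchors or a
#' two-column `chrom<TAB>anchor` table with 0-based anchor offsets.
#'
#' @param file path to the anchors file.
#' @param layout optional `Seqinfo`.
#' @param ... passed to [EnhancerSet()].
#' @return An [EnhancerSet].
#' @export
readEnhancerAnchors <- function(file, layout = NULL, ...) {
  first <- readLines(file, n = 50L)
  first <- first[!grepl("^(#|track)", first) & nzchar(first)]
  ncol1 <- length(strsplit(first[1L], "\t")[[1L]])
  if (ncol1 == 2L) {
    tab <- read.delim(file, header = FALSE, comment.char = "#",
                      col.names = c("chrom", "anchor"))
    EnhancerSet(as.character(tab$chrom), pos0 = tab$anchor,
                layout = layout, ...)
  } else {
    gr <- readBed(file, layout)
    if (any(width(gr) != 1L))
      stop("anchor BED must contain length-1 intervals")
    ids <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else names(gr)
    EnhancerSet(granges(gr), layout = layout, ids = ids, ...)
  }
}

#' Read a signal track from bedGraph or tag BED
#'
#' Both formats are reduced to the point model: a bedGraph row
#' contributes one position (the interval start) with weight equal to
#' its value; a tag BED row contributes its start with weight 1.
#'
#' @param file path to the track file.
#' @param layout `Seqinfo` with chromosome lengths (required).
#' @param format `"bedGraph"` or `"bed"`; guessed from the extension by
#'   default.
#' @return A [SignalTrack].
#' @export
readSignalTrack <- function(file, layout,
                            format = c("auto", "bedGraph", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)$", tolower(file))) "bedGraph" else "bed"
  if (format == "bedGraph") {
    gr <- rtracklayer::import(file, format = "bedGraph")
    SignalTrack(gr, weight = mcols(gr)$score, layout = layout)
  } else {
    gr <- readBed(file)
    SignalTrack(gr, weight = 1, layout = layout)
  }
}

#' Write a SignalTrack as a tag BED file
#' @param track a `SignalTrack`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeSignalTrack <- function(track, file) {
  tags <- tagPositions(track)
  df <- data.frame(chrom = as.character(seqnames(tags)),
                   start = start(tags) - 1L, end = end(tags),
                   name = "tag", score = mcols(tags)$weight)
  write.table(df, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a genes-by-tissues expression matrix
#'
#' Tab-separated, header row of tissue names, first column gene ids.
#'
#' @param file path to the TSV.
#' @return A numeric matrix (genes x tissues).
#' @export
readExpressionMatrix <- function(file) {
  tab <- read.delim(file, row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "numeric"
  if (any(m < 0, na.rm = TRUE)) stop("negative expression intensity in ", file)
  m
}

#' Write an expression matrix as TSV
#' @param m genes-by-tissues matrix.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeExpressionMatrix <- function(m, file) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read gene sets from a GMT file
#' @param file path to the GMT file (set name, description, members).
#' @return Named list of character vectors of member gene ids.
#' @export
readGmt <- function(file) fgsea::gmtPathways(file)

#' Write gene sets to GMT
#' @param sets named list of character vectors.
#' @param file output path.
#' @param descriptions optional per-set description strings.
#' @return Invisibly, `file`.
#' @export
writeGmt <- function(sets, file, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, file)
  invisible(file)
}

#' Read JASPAR-style position matrices
#'
#' Parses the common JASPAR text layouts: a `>id name` header followed
#' by four rows, either bare numbers or `A [ 4 19 0 ... ]`. Count
#' matrices are column-normalized to probabilities.
#'
#' @param file path to the matrix file.
#' @param pseudocount pseudocount stored with each motif (used by the
#'   log-odds transform at scan time).
#' @return A list of [PWMotif] objects.
#' @export
readJaspar <- function(file, pseudocount = 0.01) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' motif header found in ", file)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(header, "[ \t]+")[[1L]][1L]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4L)
      stop("motif ", id, ": expected 4 matrix rows, got ", length(body))
    rows <- lapply(body, function(ln) {
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif ", id, ": ragged matrix rows")
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    pwMotif(id, m, pseudocount = pseudocount)
  })
}
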