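#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optionally `strand`, using 0-based half-open (BED) coordinates throughout
#' the package: a fragment covering the first 100 bases of a chromosome is
#' `start = 0, end = 100`.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, 0-based exclusive end; must satisfy `start < end`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return a `data.frame` with class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL) {
  n <- length(start)
  stopifnot(length(end) == n)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be non-missing integers")
  }
  if (any(start < 0L)) stop("interval start must be >= 0")
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(sprintf("invalid interval at row %d: start (%d) >= end (%d)",
                 bad[1], start[bad[1]], end[bad[1]]))
  }
  if (is.null(strand)) strand <- rep(".", n)
  stopifnot(all(strand %in% c("+", "-", ".")))
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    strand = as.character(strand), stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Read intervals from a BED file
#'
#' Accepts 3+ tab-separated columns; columns beyond the sixth are ignored.
#' Column 4 (name) and 5 (score), when present, are kept as-is.
#'
#' @param path path to an existing BED file.
#' @return `genomic_intervals`; row order follows the file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(genomic_intervals(character(0), integer(0), integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 which(nf < 3L)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end))) {
    stop(sprintf("malformed BED line %d: non-integer coordinates",
                 which(is.na(start) | is.na(end))[1]))
  }
  strand <- rep(".", length(lines))
  if (all(nf >= 6L)) {
    s6 <- vapply(fields, `[[`, "", 6L)
    strand[s6 %in% c("+", "-")] <- s6[s6 %in% c("+", "-")]
  }
  iv <- genomic_intervals(chrom, start, end, strand)
  if (all(nf >= 4L)) iv$name <- vapply(fields, `[[`, "", 4L)
  iv
}

#' Write intervals to a BED file
#'
#' Emits chrom, start, end, plus name/score/strand when a `name` column is
#' present or any strand is set. Deterministic column order.
#'
#' @param intervals `genomic_intervals` (or compatible data frame).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- data.frame(chrom = intervals$chrom,
                     start = intervals$start,
                     end = intervals$end,
                     stringsAsFactors = FALSE)
  has_strand <- !is.null(intervals$strand) && any(intervals$strand != ".")
  if (!is.null(intervals$name) || has_strand) {
    cols$name <- if (is.null(intervals$name)) "." else intervals$name
    cols$score <- 0L
    cols$strand <- if (is.null(intervals$strand)) "." else intervals$strand
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlap width of two intervals in base pairs
#'
#' Half-open convention: abutting intervals overlap by 0 bp. Intervals on
#' different chromosomes never overlap.
#'
#' @param a,b single intervals (lists/rows with `chrom`, `start`, `end`).
#' @return integer bp, `>= 0`.
#' @export
overlap_width <- function(a, b) {
  if (as.character(a$chrom) != as.character(b$chrom)) return(0L)
  max(0L, min(a$end, b$end) - max(a$start, b$start))
}

# Vectorized interval overlap counting backed by IRanges.
# query/subject are genomic_intervals; returns an integer vector giving, per
# query row, the number of subject rows overlapping it by >= 1 bp.
count_overlaps_bp <- function(query, subject) {
  out <- integer(nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (length(si) == 0L) next
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    out[qi] <- IRanges::countOverlaps(qr, sr, minoverlap = 1L)
  }
  out
}

# As count_overlaps_bp but returns the hits (query index, subject index).
find_overlaps_idx <- function(query, subject) {
  qs <- integer(0); ss <- integer(0)
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (length(si) == 0L) next
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    h <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
    qs <- c(qs, qi[S4Vectors::queryHits(h)])
    ss <- c(ss, si[S4Vectors::subjectHits(h)])
  }
  list(query = qs, subject = ss)
}
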