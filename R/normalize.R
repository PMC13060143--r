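#' Construct a fragment set
#'
#' A fragment set is the unit of STARR/ATAC signal: BED-like fragments with a
#' sample label and a replicate label. Library size per sample is the number
#' of fragments carrying that label.
#'
#' @param chrom,start,end fragment coordinates (0-based half-open).
#' @param sample sample identifier per fragment.
#' @param replicate replicate identifier per fragment (default 1).
#' @return data.frame with class `fragment_set`.
#' @export
fragment_set <- function(chrom, start, end, sample, replicate = 1L) {
  iv <- genomic_intervals(chrom, start, end)
  n <- nrow(iv)
  out <- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                    sample = as.character(rep_len(sample, n)),
                    replicate = as.character(rep_len(replicate, n)),
                    stringsAsFactors = FALSE)
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Library sizes of a fragment set
#'
#' @param fragments a `fragment_set`.
#' @return named integer vector, fragments per sample.
#' @export
library_sizes <- function(fragments) {
  tab <- table(fragments$sample)
  stats::setNames(as.integer(tab), names(tab))
}

#' Counts-per-million normalization
#'
#' @param counts numeric matrix, rows = regions/windows, columns = samples.
#' @param lib_sizes per-column library sizes; defaults to column sums.
#' @return matrix of CPM values: `count * 1e6 / lib_size`.
#' @export
cpm_normalize <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(lib_sizes) != ncol(counts)) {
    stop("lib_sizes must have one entry per column")
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Composition-bias correction factors computed from counts in large
#' background bins (2,500 bp by convention for STARR fragment data). M-values
#' (log ratios to the reference column) are trimmed at 30% each tail and
#' A-values (average log abundance) at 5% each tail; the factor is the
#' precision-weighted mean of the surviving M-values. The reference column is
#' the one whose upper-quartile count fraction is closest to the mean across
#' columns. Factors are rescaled so their geometric mean is 1.
#'
#' @param bin_counts integer matrix, bins x samples, >= 2 columns.
#' @param lib_sizes per-column library sizes; defaults to column sums.
#' @param trim_m,trim_a tail trim fractions for M and A values.
#' @return numeric vector of positive per-column factors, geometric mean 1.
#' @export
tmm_norm_factors <- function(bin_counts, lib_sizes = colSums(bin_counts),
                             trim_m = 0.3, trim_a = 0.05) {
  x <- as.matrix(bin_counts)
  if (ncol(x) < 2L) stop("TMM requires >= 2 columns")
  if (any(colSums(x) == 0)) stop("column with all-zero bins")
  # reference: upper-quartile (of nonzero-scaled counts) closest to mean
  uq <- apply(sweep(x, 2L, lib_sizes, "/"), 2L, function(v) {
    stats::quantile(v[v > 0], 0.75)
  })
  ref <- which.min(abs(uq - mean(uq)))

  f <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(x[, j], x[, ref], lib_sizes[j], lib_sizes[ref], trim_m, trim_a)
  }, numeric(1))
  f / exp(mean(log(f)))
}

# one TMM factor of column `obs` against column `ref` (edgeR-style weighting)
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / n_obs; p_r <- ref / n_ref
  m <- log2(p_o / p_r)
  a <- (log2(p_o) + log2(p_r)) / 2
  if (max(abs(m)) < 1e-10) return(1)
  # asymptotic delta-method variance of M as weight
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep2 <- rank(m, ties.method = "first") >= lo_m &
    rank(m, ties.method = "first") <= hi_m &
    rank(a, ties.method = "first") >= lo_a &
    rank(a, ties.method = "first") <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Count fragments into equal-width genomic bins
#'
#' Helper producing the background-bin count matrix consumed by
#' [tmm_norm_factors()]. Bins tile each chromosome from coordinate 0.
#'
#' @param fragments `fragment_set`.
#' @param bin_width bin width in bp (default 2500).
#' @return list with `counts` (bins x samples matrix) and `bins` intervals.
#' @export
bin_counts <- function(fragments, bin_width = 2500L) {
  bins_list <- lapply(unique(fragments$chrom), function(chr) {
    maxend <- max(fragments$end[fragments$chrom == chr])
    nb <- ceiling(maxend / bin_width)
    genomic_intervals(rep(chr, nb), (seq_len(nb) - 1L) * bin_width,
                      seq_len(nb) * bin_width)
  })
  bins <- do.call(rbind, bins_list)
  class(bins) <- c("genomic_intervals", "data.frame")
  samples <- sort(unique(fragments$sample))
  counts <- sapply(samples, function(s) {
    count_overlaps_bp(bins, fragments[fragments$sample == s, , drop = FALSE])
  })
  counts <- matrix(as.integer(counts), nrow = nrow(bins),
                   dimnames = list(NULL, samples))
  list(counts = counts, bins = bins)
}
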