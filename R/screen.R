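#' Crop reads to the protospacer
#'
#' Truncates each read to its first `crop` bases; reads shorter than `crop`
#' are dropped (their count is reported in attribute `n_dropped`).
#'
#' @param reads character vector of read sequences.
#' @param crop protospacer length (default 20).
#' @return cropped sequences.
#' @export
extract_protospacers <- function(reads, crop = 20L) {
  keep <- nchar(reads) >= crop
  out <- substr(reads[keep], 1L, crop)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Count protospacer reads against a guide library
#'
#' Exact policy: hash lookup of the read in the library. One-mismatch
#' policy: a read additionally counts toward a guide at Hamming distance 1
#' when that guide is unique; reads within distance 1 of more than one
#' guide are discarded as ambiguous. Counting conserves reads:
#' `matched + ambiguous + unmatched = total`.
#'
#' @param protospacers cropped read sequences.
#' @param library_guides character vector of unique library protospacers.
#' @param policy `"exact"` (default) or `"one-mismatch"`.
#' @return integer vector of per-guide counts (named by guide); attributes
#'   `n_matched`, `n_ambiguous`, `n_unmatched`.
#' @export
count_guides <- function(protospacers, library_guides,
                         policy = c("exact", "one-mismatch")) {
  policy <- match.arg(policy)
  if (anyDuplicated(library_guides)) stop("library protospacers must be unique")
  counts <- stats::setNames(integer(length(library_guides)), library_guides)
  hit <- match(protospacers, library_guides)
  exact_tab <- table(hit[!is.na(hit)])
  counts[as.integer(names(exact_tab))] <- as.integer(exact_tab)
  n_matched <- sum(!is.na(hit))
  n_ambig <- 0L
  if (policy == "one-mismatch") {
    rest <- unique(protospacers[is.na(hit)])
    if (length(rest) > 0L) {
      lib_mat <- do.call(rbind, strsplit(library_guides, "", fixed = TRUE))
      rest_tab <- table(protospacers[is.na(hit)])
      for (r in rest) {
        rc <- strsplit(r, "", fixed = TRUE)[[1]]
        d <- rowSums(t(t(lib_mat) != rc))
        near <- which(d == 1L)
        nr <- as.integer(rest_tab[[r]])
        if (length(near) == 1L) {
          counts[near] <- counts[near] + nr
          n_matched <- n_matched + nr
        } else if (length(near) > 1L) {
          n_ambig <- n_ambig + nr
        }
      }
    }
  }
  names(counts) <- library_guides
  attr(counts, "n_matched") <- n_matched
  attr(counts, "n_ambiguous") <- n_ambig
  attr(counts, "n_unmatched") <- length(protospacers) - n_matched - n_ambig
  counts
}

#' Median-of-ratios size factors
#'
#' Per sample, the median ratio of its counts to the geometric-mean
#' reference profile, computed over guides with all-positive counts.
#'
#' @param counts integer matrix guides x samples.
#' @return numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no guide with positive counts in all samples")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2L, function(col) exp(stats::median(col - ref)))
}

#' Test guides for differential abundance between sorted bins
#'
#' Per guide, a negative-binomial log-linear model of counts on bin (hi vs
#' lo) with a replicate covariate when two or more replicate pairs exist,
#' offset by log size factors. Dispersions are trend-shrunk
#' method-of-moments estimates; inference is a Wald t test with prior df
#' added. Positive log2FC means enrichment in the hi bin. This is a
#' simplified stand-in for DESeq2: calibration and recovery are the
#' contract, not numerical equivalence.
#'
#' @param counts integer matrix guides x samples.
#' @param design data.frame with `sample`, `replicate`, `bin` (hi/lo).
#' @param sf size factors (default [size_factors()]).
#' @param prior_df shrinkage prior degrees of freedom (default 20).
#' @return data.frame: guide, log2fc, p, padj. Guides with all-zero counts
#'   get NA statistics.
#' @export
test_guides <- function(counts, design, sf = NULL, prior_df = 20) {
  counts <- as.matrix(counts)[, design$sample, drop = FALSE]
  stopifnot(all(design$bin %in% c("hi", "lo")))
  if (is.null(sf)) sf <- size_factors(counts)
  offsets <- log(sf)
  bin <- as.numeric(design$bin == "hi")
  X <- cbind(intercept = 1, bin = bin)
  n_reps <- length(unique(design$replicate))
  if (n_reps >= 2L) {
    rep_f <- factor(design$replicate)
    X <- cbind(X, stats::model.matrix(~rep_f)[, -1, drop = FALSE])
  }
  keep <- rowSums(counts) > 0
  # dispersion: group structure of bin only (replicate absorbed in trend);
  # with a single sample per bin there are no residual df, so fall back to
  # a fixed mild dispersion (effect estimates remain exact ratios)
  dsp <- if (ncol(counts) > 2L) {
    .nb_shrunk_dispersion(counts[keep, , drop = FALSE], design$bin, offsets,
                          prior_df = prior_df)
  } else {
    list(dispersion = rep(0.05, sum(keep)), prior_df = prior_df)
  }
  df <- ncol(counts) - ncol(X) + dsp$prior_df
  res <- matrix(NA_real_, nrow(counts), 3L,
                dimnames = list(NULL, c("est", "se", "p")))
  kidx <- which(keep)
  for (ii in seq_along(kidx)) {
    i <- kidx[ii]
    res[i, ] <- .nb_wald_fit(counts[i, ], X, offsets,
                             dsp$dispersion[ii], coef = 2L, df = df)
  }
  guides <- rownames(counts)
  if (is.null(guides)) guides <- sprintf("g%d", seq_len(nrow(counts)))
  out <- data.frame(guide = guides, log2fc = res[, "est"] / log(2),
                    p = res[, "p"], stringsAsFactors = FALSE)
  out$padj <- NA_real_
  out$padj[keep] <- stats::p.adjust(out$p[keep], method = "BH")
  out
}

#' Aggregate guide-level results to element-level calls
#'
#' Per region: number of guides tested, number significant, mean and median
#' guide log2FC, and a significance flag (>= `min_sig_guides` guides at
#' `padj < sig_threshold`). Non-targeting controls are summarized
#' separately as the empirical null.
#'
#' @param guide_results output of [test_guides()].
#' @param library guide library table with `guide_id` and `region_id`
#'   (`region_id == "NTC"` marks controls), as from [assemble_library()].
#' @param sig_threshold padj cutoff (default 0.05).
#' @param min_sig_guides guides required to call an element (default 1).
#' @return list: `elements` (data.frame per region), `ntc` (summary list).
#' @export
aggregate_elements <- function(guide_results, library, sig_threshold = 0.05,
                               min_sig_guides = 1L) {
  m <- merge(guide_results, library[, c("guide_id", "region_id")],
             by.x = "guide", by.y = "guide_id")
  is_ntc <- m$region_id == "NTC"
  targ <- m[!is_ntc, , drop = FALSE]
  per <- lapply(split(targ, targ$region_id), function(g) {
    sig <- !is.na(g$padj) & g$padj < sig_threshold
    data.frame(region_id = g$region_id[1], n_guides = nrow(g),
               n_sig = sum(sig),
               mean_log2fc = mean(g$log2fc, na.rm = TRUE),
               median_log2fc = stats::median(g$log2fc, na.rm = TRUE),
               significant = sum(sig) >= min_sig_guides,
               stringsAsFactors = FALSE)
  })
  elements <- do.call(rbind, per)
  rownames(elements) <- NULL
  ntc <- m[is_ntc, , drop = FALSE]
  ntc_summary <- list(
    n_guides = nrow(ntc),
    n_sig = sum(!is.na(ntc$padj) & ntc$padj < sig_threshold),
    mean_log2fc = if (nrow(ntc)) mean(ntc$log2fc, na.rm = TRUE) else NA_real_)
  list(elements = elements, ntc = ntc_summary)
}
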