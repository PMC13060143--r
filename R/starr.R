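#' Filter fragments by length
#'
#' STARR-seq RNA output libraries carry an overabundance of short (< 140 bp)
#' fragments relative to the input DNA; both libraries are therefore
#' restricted to a common length range before counting. Bounds are inclusive.
#'
#' @param fragments `fragment_set`.
#' @param min_len,max_len inclusive length bounds (defaults 150 and 800 bp).
#' @return filtered `fragment_set`; attribute `retained` holds the
#'   per-sample retained fragment counts.
#' @export
filter_fragments <- function(fragments, min_len = 150L, max_len = 800L) {
  if (min_len >= max_len) stop("min_len must be < max_len")
  len <- fragments$end - fragments$start
  out <- fragments[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(fragments)
  attr(out, "retained") <- table(factor(out$sample,
                                        levels = sort(unique(fragments$sample))))
  out
}

#' Build sliding windows over a peak set
#'
#' Tiles each chromosome with fixed-width windows whose starts are multiples
#' of the step from coordinate 0 (a deterministic phase convention), keeping
#' only windows overlapping at least one peak by >= 1 bp.
#'
#' @param peaks `genomic_intervals` union peak set.
#' @param width window width in bp (default 50).
#' @param step stride in bp (default 25); must satisfy `width >= step`.
#' @return `genomic_intervals` of windows, sorted by chrom then start.
#' @export
make_windows <- function(peaks, width = 50L, step = 25L) {
  if (width < step) stop("width must be >= step")
  if (nrow(peaks) == 0L) {
    return(genomic_intervals(character(0), integer(0), integer(0)))
  }
  parts <- lapply(unique(peaks$chrom), function(chr) {
    p <- peaks[peaks$chrom == chr, , drop = FALSE]
    t_all <- unlist(lapply(seq_len(nrow(p)), function(i) {
      t_min <- max(0L, floor((p$start[i] - width) / step) + 1L)
      t_max <- ceiling(p$end[i] / step) - 1L
      if (t_max < t_min) return(integer(0))
      t_min:t_max
    }))
    t_all <- sort(unique(t_all))
    genomic_intervals(rep(chr, length(t_all)), t_all * step,
                      t_all * step + width)
  })
  out <- do.call(rbind, parts)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Count fragments overlapping each window
#'
#' A fragment contributes to every window it overlaps by >= 1 bp, so one
#' fragment typically counts in several adjacent sliding windows.
#'
#' @param fragments `fragment_set` (already length-filtered).
#' @param windows `genomic_intervals`.
#' @param samples optional sample ordering for the columns.
#' @return integer matrix, windows x samples.
#' @export
count_in_windows <- function(fragments, windows,
                             samples = sort(unique(fragments$sample))) {
  counts <- vapply(samples, function(s) {
    count_overlaps_bp(windows, fragments[fragments$sample == s, , drop = FALSE])
  }, integer(nrow(windows)))
  matrix(as.integer(counts), nrow = nrow(windows),
         dimnames = list(NULL, samples))
}

#' Test windows for differential activity against input DNA
#'
#' Fits, per window and per subset, a negative-binomial log-linear model of
#' the subset's RNA counts against the input DNA counts, with log effective
#' library sizes (library size x normalization factor) as offsets.
#' Dispersions are method-of-moments estimates shrunk toward an abundance
#' trend; inference is a Wald t test whose degrees of freedom add the
#' shrinkage prior df to the residual df. This is a deliberate
#' simplification of the quasi-likelihood machinery used by edgeR/csaw: the
#' contract is type-I calibration and planted-effect recovery, not numerical
#' equivalence.
#'
#' @param counts integer matrix windows x samples.
#' @param design data.frame with columns `sample` and `group`; `group` is
#'   `"input"` for DNA libraries and the subset name for RNA libraries.
#' @param lib_sizes per-sample library sizes (named; default column sums).
#' @param norm_factors per-sample TMM factors (named; default 1).
#' @param prior_df shrinkage prior degrees of freedom (default 10).
#' @return data.frame: window (row index), subset, log2fc, p, abundance
#'   (average log2 CPM). All-zero windows are excluded; their count is in
#'   attribute `n_excluded`.
#' @export
test_windows <- function(counts, design, lib_sizes = colSums(counts),
                         norm_factors = NULL, prior_df = 10) {
  counts <- as.matrix(counts)[, design$sample, drop = FALSE]
  if (is.null(norm_factors)) {
    norm_factors <- stats::setNames(rep(1, nrow(design)), design$sample)
  }
  if (sum(design$group == "input") < 1L) stop("design needs input samples")
  offsets <- log(lib_sizes[design$sample] * norm_factors[design$sample])
  keep <- rowSums(counts) > 0
  n_excluded <- sum(!keep)
  kc <- counts[keep, , drop = FALSE]
  widx <- which(keep)

  dsp <- .nb_shrunk_dispersion(kc, design$group, offsets, prior_df = prior_df)
  ab <- log2(rowMeans(sweep(kc, 2L, exp(offsets), "/")) * 1e6 + 0.5)
  subsets <- setdiff(unique(design$group), "input")

  out <- vector("list", length(subsets))
  for (si in seq_along(subsets)) {
    s <- subsets[si]
    j <- which(design$group %in% c("input", s))
    df <- length(j) - 2L + dsp$prior_df
    res <- .nb_two_group_test(kc[, j, drop = FALSE],
                              design$group[j] == s, offsets[j],
                              dsp$dispersion, df)
    out[[si]] <- data.frame(window = widx, subset = s,
                            log2fc = res$est / log(2),
                            p = pmin(pmax(res$p, 1e-300), 1),
                            abundance = ab, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  attr(res, "dispersion") <- dsp$dispersion
  res
}

#' Merge adjacent windows into clusters
#'
#' Windows whose gap (`next.start - this.end` on sorted windows) is at most
#' `tolerance` are chained into one cluster; with tolerance 0, abutting
#' half-open windows merge and windows separated by >= 1 bp do not. Any
#' chain spanning more than `max_width` bp is split at window boundaries
#' into `ceiling(span / max_width)` sub-clusters of near-equal window count.
#'
#' @param windows `genomic_intervals`, need not be sorted.
#' @param tolerance maximum gap in bp (default 0).
#' @param max_width maximum merged span in bp (default 3000).
#' @return list: `cluster` (integer id per input window row, in input
#'   order), `regions` (`genomic_intervals`, one row per cluster id).
#' @export
merge_windows <- function(windows, tolerance = 0L, max_width = 3000L) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  n <- nrow(windows)
  ord <- order(windows$chrom, windows$start, windows$end)
  cl_sorted <- integer(n)
  nxt <- 0L
  prev_chr <- ""
  prev_end <- -Inf
  buf <- integer(0)  # sorted-order indices of the open chain

  flush <- function(buf, nxt, cl_sorted) {
    if (length(buf) == 0L) return(list(nxt = nxt, cl = cl_sorted))
    span <- max(windows$end[ord[buf]]) - min(windows$start[ord[buf]])
    k <- max(1L, ceiling(span / max_width))
    pieces <- split(buf, ceiling(seq_along(buf) / (length(buf) / k)))
    for (p in pieces) {
      nxt <- nxt + 1L
      cl_sorted[p] <- nxt
    }
    list(nxt = nxt, cl = cl_sorted)
  }

  for (i in seq_len(n)) {
    w <- ord[i]
    if (windows$chrom[w] != prev_chr ||
        windows$start[w] - prev_end > tolerance) {
      r <- flush(buf, nxt, cl_sorted); nxt <- r$nxt; cl_sorted <- r$cl
      buf <- integer(0)
      prev_end <- -Inf
    }
    buf <- c(buf, i)
    prev_chr <- windows$chrom[w]
    prev_end <- max(prev_end, windows$end[w])
  }
  r <- flush(buf, nxt, cl_sorted); nxt <- r$nxt; cl_sorted <- r$cl

  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  regions <- do.call(rbind, lapply(seq_len(nxt), function(k) {
    idx <- which(cluster == k)
    data.frame(chrom = windows$chrom[idx[1]],
               start = min(windows$start[idx]),
               end = max(windows$end[idx]), strand = ".",
               stringsAsFactors = FALSE)
  }))
  class(regions) <- c("genomic_intervals", "data.frame")
  list(cluster = cluster, regions = regions)
}

#' Weighted-Holm adjusted p-values
#'
#' Holm's step-down procedure with weights interpreted as relative
#' alpha-spending shares: hypotheses are visited in increasing order of
#' `p/w`, each adjusted p is `p * (remaining weight) / w`, and adjusted
#' values are made monotone and capped at 1.
#'
#' @param p p-values.
#' @param w positive weights (default equal).
#' @return adjusted p-values in the input order.
#' @export
weighted_holm <- function(p, w = rep(1, length(p))) {
  stopifnot(length(p) == length(w), all(w > 0))
  ord <- order(p / w)
  remaining <- rev(cumsum(rev(w[ord])))
  adj <- pmin(1, p[ord] * remaining / w[ord])
  adj <- cummax(adj)
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Combine window p-values within a merged region
#'
#' Region-level evidence requires several windows to be individually
#' significant: the combined p-value is the k-th smallest weighted-Holm
#' adjusted member p-value with
#' `k = min(n, max(min_sig_n, ceiling(0.4 n)))`, so a region's combined p
#' is only small when at least k member windows are small after the
#' multiplicity adjustment. The summit window (highest abundance) is
#' upweighted; the representative log2 fold change comes from the best-test
#' window (smallest adjusted p, ties broken toward larger |log2FC|).
#'
#' @param p member window p-values.
#' @param log2fc member window log2 fold changes.
#' @param abundance member window abundances (for summit upweighting);
#'   NULL for equal weights.
#' @param min_sig_n minimum significant windows per region (default 3).
#' @param summit_weight weight of the summit window (default 4, others 1).
#' @return list: `p` (combined), `rep_log2fc`, `best_window` (index into
#'   the member vectors), `k`.
#' @export
combine_region_pvalues <- function(p, log2fc, abundance = NULL,
                                   min_sig_n = 3L, summit_weight = 4) {
  n <- length(p)
  stopifnot(n >= 1L, length(log2fc) == n)
  w <- rep(1, n)
  if (!is.null(abundance) && n > 1L) {
    w[which.max(abundance)] <- summit_weight
  }
  adj <- weighted_holm(p, w)
  k <- min(n, max(min_sig_n, ceiling(0.4 * n)))
  comb <- sort(adj, partial = k)[k]
  best <- which(adj == min(adj))
  if (length(best) > 1L) best <- best[which.max(abs(log2fc[best]))]
  list(p = comb, rep_log2fc = log2fc[best], best_window = best, k = k)
}

#' Classify regions by FDR and effect direction
#'
#' Benjamini-Hochberg adjustment across regions, then: `active` when
#' FDR <= threshold and representative log2FC > 0; `repressive` when
#' FDR <= threshold and log2FC < 0; otherwise `not-significant`.
#'
#' @param regions data.frame with columns `combined_p` and `rep_log2fc`.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return the input with added `fdr` and `class` columns.
#' @export
classify_regions <- function(regions, fdr_threshold = 0.05) {
  regions$fdr <- stats::p.adjust(regions$combined_p, method = "BH")
  regions$class <- ifelse(
    regions$fdr <= fdr_threshold & regions$rep_log2fc > 0, "active",
    ifelse(regions$fdr <= fdr_threshold & regions$rep_log2fc < 0,
           "repressive", "not-significant"))
  regions
}

#' Run the full STARR-seq activity pipeline
#'
#' Fragment filtering, sliding-window counting over the union peak set, TMM
#' normalization on background bins, per-window NB testing of each subset
#' against input DNA, window merging, region-level p-value combination, and
#' FDR classification.
#'
#' @param fragments `fragment_set` with input and RNA samples.
#' @param peaks union peak set (`genomic_intervals`).
#' @param design data.frame with `sample` and `group` (`"input"` or subset).
#' @param window,step window geometry in bp.
#' @param min_len,max_len fragment length filter bounds.
#' @param merge_tol,max_width window merge parameters in bp.
#' @param min_sig_n minimum significant windows per region.
#' @param fdr_threshold region FDR cutoff.
#' @param tmm use TMM background-bin normalization factors (default TRUE).
#' @return list: `windows`, `window_stats`, `regions` (one row per region x
#'   subset with combined_p, fdr, rep_log2fc, n_windows, class), `cluster`.
#' @export
starr_pipeline <- function(fragments, peaks, design, window = 50L, step = 25L,
                           min_len = 150L, max_len = 800L, merge_tol = 0L,
                           max_width = 3000L, min_sig_n = 3L,
                           fdr_threshold = 0.05, tmm = TRUE) {
  fr <- filter_fragments(fragments, min_len, max_len)
  win <- make_windows(peaks, width = window, step = step)
  counts <- count_in_windows(fr, win, samples = design$sample)
  libs <- stats::setNames(as.integer(table(factor(fr$sample,
                                                  levels = design$sample))),
                          design$sample)
  nf <- if (tmm && ncol(counts) >= 2L) {
    bc <- bin_counts(fr)$counts[, design$sample, drop = FALSE]
    tmm_norm_factors(bc, lib_sizes = libs)
  } else {
    stats::setNames(rep(1, nrow(design)), design$sample)
  }
  names(nf) <- design$sample
  ws <- test_windows(counts, design, lib_sizes = libs, norm_factors = nf)
  mg <- merge_windows(win, tolerance = merge_tol, max_width = max_width)

  regions <- list()
  for (s in unique(ws$subset)) {
    sub <- ws[ws$subset == s, , drop = FALSE]
    cl <- mg$cluster[sub$window]
    per <- lapply(split(seq_len(nrow(sub)), cl), function(idx) {
      cc <- combine_region_pvalues(sub$p[idx], sub$log2fc[idx],
                                   abundance = sub$abundance[idx],
                                   min_sig_n = min_sig_n)
      data.frame(combined_p = cc$p, rep_log2fc = cc$rep_log2fc,
                 n_windows = length(idx))
    })
    df <- do.call(rbind, per)
    cid <- as.integer(names(per))
    df <- cbind(data.frame(chrom = mg$regions$chrom[cid],
                           start = mg$regions$start[cid],
                           end = mg$regions$end[cid],
                           region = cid, subset = s,
                           stringsAsFactors = FALSE), df)
    regions[[s]] <- classify_regions(df, fdr_threshold)
  }
  regions <- do.call(rbind, regions)
  rownames(regions) <- NULL
  list(windows = win, window_stats = ws, regions = regions,
       cluster = mg$cluster, norm_factors = nf, lib_sizes = libs)
}
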