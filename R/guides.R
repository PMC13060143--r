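#' Filter guide candidates by specificity and banned substrings
#'
#' Removes candidates whose off-target specificity score is below the
#' threshold (strictly: a score exactly at the threshold is kept) or whose
#' protospacer contains a banned repeat (G homopolymer of 5, or TTTT which
#' terminates Pol III transcription).
#'
#' @param candidates data.frame with `protospacer` and `specificity`.
#' @param min_specificity retain scores >= this (default 0.2).
#' @param banned_substrings character vector (default GGGGG, TTTT).
#' @return filtered candidate data.frame.
#' @export
filter_candidates <- function(candidates, min_specificity = 0.2,
                              banned_substrings = c("GGGGG", "TTTT")) {
  keep <- candidates$specificity >= min_specificity
  for (b in banned_substrings) {
    keep <- keep & !grepl(b, candidates$protospacer, fixed = TRUE)
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chromatin-accessibility score for guide footprints
#'
#' Per subset, the mean over replicates of the CPM-sum of ATAC fragments
#' overlapping the 20 bp guide footprint by >= 1 bp; the final score is the
#' maximum of the subset means.
#'
#' @param candidates data.frame with `chrom`, `start`, `end` footprints.
#' @param fragments `fragment_set` whose `sample` column names the subset
#'   and `replicate` the biological replicate.
#' @return numeric vector of accessibility scores (CPM), one per candidate.
#' @export
accessibility_score <- function(candidates, fragments) {
  foot <- genomic_intervals(candidates$chrom, candidates$start, candidates$end)
  subsets <- unique(fragments$sample)
  per_subset <- sapply(subsets, function(s) {
    fs <- fragments[fragments$sample == s, , drop = FALSE]
    reps <- unique(fs$replicate)
    rep_cpm <- sapply(reps, function(r) {
      fr <- fs[fs$replicate == r, , drop = FALSE]
      count_overlaps_bp(foot, fr) * 1e6 / nrow(fr)
    })
    rowMeans(matrix(rep_cpm, nrow = nrow(foot)))
  })
  apply(matrix(per_subset, nrow = nrow(foot)), 1L, max)
}

#' Greedy non-overlapping guide selection within a region
#'
#' Candidates are ranked by descending accessibility score (ties: smaller
#' start coordinate, then lexicographic protospacer) and accepted in rank
#' order if their 20 bp footprint overlaps every previously accepted guide
#' by at most `max_overlap` bp, stopping at `cap` guides.
#'
#' @param candidates data.frame with `start`, `end`, `protospacer`, and the
#'   score column.
#' @param cap maximum guides to retain (10 genome-scale, 15 targeted).
#' @param max_overlap maximum pairwise footprint overlap in bp (default 10).
#' @param score_col column used for ranking (default "accessibility").
#' @return selected rows with a `rank_in_peak` column (acceptance order).
#' @export
select_guides <- function(candidates, cap = 10L, max_overlap = 10L,
                          score_col = "accessibility") {
  if (cap < 1L) stop("cap must be >= 1")
  if (nrow(candidates) == 0L) return(cbind(candidates, rank_in_peak = integer(0)))
  ord <- order(-candidates[[score_col]], candidates$start,
               candidates$protospacer)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= cap) break
    ov <- pmax(0L, pmin(candidates$end[sel], candidates$end[i]) -
                 pmax(candidates$start[sel], candidates$start[i]))
    if (all(ov <= max_overlap)) sel <- c(sel, i)
  }
  out <- candidates[sel, , drop = FALSE]
  out$rank_in_peak <- seq_along(sel)
  rownames(out) <- NULL
  out
}

# GC count (0..20) of each protospacer
.gc_count <- function(seqs) {
  vapply(strsplit(seqs, "", fixed = TRUE),
         function(ch) sum(ch %in% c("G", "C")), integer(1))
}

# TRUE when the 20-mer (or its reverse complement) matches the genome with
# at most `max_mismatch` mismatches
.matches_genome <- function(seq20, genome_dna, max_mismatch = 1L) {
  pat <- Biostrings::DNAString(seq20)
  hits <- Biostrings::countPattern(pat, genome_dna,
                                   max.mismatch = max_mismatch)
  if (hits > 0L) return(TRUE)
  Biostrings::countPattern(Biostrings::reverseComplement(pat), genome_dna,
                           max.mismatch = max_mismatch) > 0L
}

#' Generate GC-matched non-targeting control guides
#'
#' Draws random 20-mers whose GC-count distribution matches the targeting
#' guides (stratified sampling by GC count), rejecting any candidate that
#' contains a banned substring or matches the genome on either strand under
#' the configured policy (default: no exact and no single-mismatch match).
#'
#' @param targeting character vector of targeting protospacers.
#' @param n_ntc number of NTCs to generate.
#' @param genome genome sequence (single string) to exclude matches against.
#' @param max_mismatch matches with up to this many mismatches are excluded
#'   (default 1).
#' @param banned_substrings as in [filter_candidates()].
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget multiplier (default 1000).
#' @return character vector of `n_ntc` NTC protospacers.
#' @export
generate_ntc <- function(targeting, n_ntc, genome, max_mismatch = 1L,
                         banned_substrings = c("GGGGG", "TTTT"), seed = 1L,
                         max_tries = 1000L) {
  set.seed(seed)
  gc_pool <- .gc_count(targeting)
  genome_dna <- Biostrings::DNAString(genome)
  out <- character(0)
  tries <- 0L
  while (length(out) < n_ntc) {
    tries <- tries + 1L
    if (tries > max_tries * n_ntc) {
      stop("NTC rejection rate too high; relax the matching policy")
    }
    gc <- sample(gc_pool, 1L)
    pos <- sample.int(20L, gc)
    ch <- rep("", 20L)
    ch[pos] <- sample(c("G", "C"), gc, replace = TRUE)
    ch[-pos] <- sample(c("A", "T"), 20L - gc, replace = TRUE)
    cand <- paste(ch, collapse = "")
    if (any(vapply(banned_substrings, grepl, TRUE, x = cand, fixed = TRUE))) next
    if (.matches_genome(cand, genome_dna, max_mismatch)) next
    if (cand %in% out) next
    out <- c(out, cand)
  }
  out
}

#' Assemble the final guide library
#'
#' Combines per-region selected guides with NTCs into one table. The NTC
#' count is `round(fraction * total)` where total includes the NTCs
#' themselves (`n_ntc = round(n_targeting * fraction / (1 - fraction))`).
#' Duplicate protospacers across regions are deduplicated with a warning
#' (the first region keeps the guide).
#'
#' @param selected data.frame of selected targeting guides with
#'   `region_id`, `chrom`, `start`, `end`, `strand`, `protospacer`,
#'   `specificity`, `accessibility`, `rank_in_peak`.
#' @param genome genome sequence for the NTC alignment check.
#' @param ntc_fraction NTC share of the final library (default 0.05).
#' @param seed integer seed for NTC generation.
#' @return list: `library` (single table, `is_ntc` flag), `summary`
#'   (n_targeting, n_ntc, ntc_fraction).
#' @export
assemble_library <- function(selected, genome, ntc_fraction = 0.05,
                             seed = 1L) {
  if (nrow(selected) == 0L) stop("no targeting guides selected")
  dup <- duplicated(selected$protospacer)
  if (any(dup)) {
    warning(sum(dup), " duplicate protospacers removed across regions")
    selected <- selected[!dup, , drop = FALSE]
  }
  n_t <- nrow(selected)
  n_ntc <- round(n_t * ntc_fraction / (1 - ntc_fraction))
  ntc <- generate_ntc(selected$protospacer, n_ntc, genome, seed = seed)
  lib <- data.frame(
    guide_id = c(sprintf("g%05d", seq_len(n_t)),
                 sprintf("NTC%04d", seq_len(n_ntc))),
    region_id = c(as.character(selected$region_id), rep("NTC", n_ntc)),
    chrom = c(selected$chrom, rep(NA, n_ntc)),
    start = c(selected$start, rep(NA, n_ntc)),
    end = c(selected$end, rep(NA, n_ntc)),
    strand = c(selected$strand, rep(NA, n_ntc)),
    protospacer = c(selected$protospacer, ntc),
    specificity = c(selected$specificity, rep(NA, n_ntc)),
    accessibility = c(selected$accessibility, rep(NA, n_ntc)),
    rank_in_peak = c(selected$rank_in_peak, rep(NA, n_ntc)),
    is_ntc = rep(c(FALSE, TRUE), c(n_t, n_ntc)),
    stringsAsFactors = FALSE)
  list(library = lib,
       summary = list(n_targeting = n_t, n_ntc = n_ntc,
                      ntc_fraction = n_ntc / (n_t + n_ntc)))
}

#' Design a guide library end-to-end
#'
#' Candidate enumeration (NGG scan), specificity/repeat filtering,
#' accessibility scoring and greedy selection per region, plus GC-matched
#' NTCs.
#'
#' @param genome genome sequence string.
#' @param regions target regions (`genomic_intervals`).
#' @param fragments ATAC `fragment_set` (samples = subsets, replicates set).
#' @param cap guides per region (default 10).
#' @param max_overlap maximum footprint overlap (default 10).
#' @param min_specificity specificity filter (default 0.2).
#' @param ntc_fraction NTC share of the final library (default 0.05).
#' @param seed integer seed.
#' @return as [assemble_library()], plus `candidates` (post-filter).
#' @export
design_guides <- function(genome, regions, fragments, cap = 10L,
                          max_overlap = 10L, min_specificity = 0.2,
                          ntc_fraction = 0.05, seed = 1L) {
  cand <- simulate_guide_candidates(genome, regions, seed = seed)
  cand <- filter_candidates(cand, min_specificity)
  cand$accessibility <- accessibility_score(cand, fragments)
  sel <- do.call(rbind, lapply(split(cand, cand$region_id), select_guides,
                               cap = cap, max_overlap = max_overlap))
  rownames(sel) <- NULL
  out <- assemble_library(sel, genome, ntc_fraction, seed = seed)
  out$candidates <- cand
  out
}
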