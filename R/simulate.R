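#' Simulate a random genome sequence
#'
#' I.i.d. nucleotides with a configurable expected GC fraction. Used as the
#' backdrop for guide-candidate enumeration and non-targeting-control checks.
#'
#' @param length sequence length in bp, > 0.
#' @param gc expected GC fraction, strictly inside (0, 1).
#' @param seed integer seed.
#' @return single character string of A/C/G/T.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = 1L) {
  if (length <= 0) stop("length must be > 0")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Simulate per-region activity ground truth
#'
#' Assigns each region a class and a per-subset activity multiplier:
#' `inactive` regions have multiplier 1 everywhere, `shared-active` regions
#' are elevated in every subset, `subset-specific` regions in exactly one,
#' and `repressive` regions are attenuated in every subset.
#'
#' @param n_regions number of regions.
#' @param subsets character vector of subset names (default the five CD4
#'   polarization states).
#' @param proportions named proportions for the four classes; must sum to 1.
#' @param active_mult multiplier for active classes (default 4).
#' @param repressive_mult multiplier for the repressive class (default 0.25).
#' @param seed integer seed.
#' @return data.frame: `region`, `class`, `specific_subset` (NA unless
#'   subset-specific), and one `mult_<subset>` column per subset.
#' @export
simulate_activity_truth <- function(n_regions,
                                    subsets = c("Th0", "Th1", "Th2", "Th17", "Treg"),
                                    proportions = c(inactive = 0.77,
                                                    `shared-active` = 0.12,
                                                    `subset-specific` = 0.06,
                                                    repressive = 0.05),
                                    active_mult = 4, repressive_mult = 0.25,
                                    seed = 1L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8)
  set.seed(seed)
  cls <- sample(names(proportions), n_regions, replace = TRUE,
                prob = proportions)
  mult <- matrix(1, n_regions, length(subsets),
                 dimnames = list(NULL, paste0("mult_", subsets)))
  spec <- rep(NA_character_, n_regions)
  mult[cls == "shared-active", ] <- active_mult
  mult[cls == "repressive", ] <- repressive_mult
  idx <- which(cls == "subset-specific")
  if (length(idx)) {
    pick <- sample.int(length(subsets), length(idx), replace = TRUE)
    mult[cbind(idx, pick)] <- active_mult
    spec[idx] <- subsets[pick]
  }
  cbind(data.frame(region = seq_len(n_regions), class = cls,
                   specific_subset = spec, stringsAsFactors = FALSE),
        as.data.frame(mult))
}

# fragment lengths for the main (plasmid-insert) mode: truncated to [150,800]
.sim_main_lengths <- function(n) {
  len <- 150 + round(stats::rgamma(n, shape = 2, scale = 80))
  pmin(pmax(len, 150L), 800L)
}

# short-fragment contaminant mode (< 140 bp), RNA outputs only
.sim_short_lengths <- function(n) {
  pmin(pmax(round(stats::rnorm(n, 100, 20)), 50L), 139L)
}

# place n fragments of given lengths with midpoints uniform in a peak
.sim_place <- function(chrom, p_start, p_end, len) {
  mid <- p_start + floor(stats::runif(length(len)) * (p_end - p_start))
  start <- pmax(0L, mid - floor(len / 2))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), stringsAsFactors = FALSE)
}

#' Simulate a STARR-seq experiment with planted activity
#'
#' Generates an input DNA fragment library (uniform over peaks, lengths in a
#' 150-800 bp mode) and per-subset RNA output libraries whose per-peak rates
#' are the input rates times the planted multiplier. RNA outputs additionally
#' carry a short-fragment (< 140 bp) contaminant mode, mirroring the
#' input/output length asymmetry seen in real reporter libraries; the
#' downstream length filter removes it. Peak-level fragment counts are
#' Poisson, with a mild gamma replicate-level overdispersion.
#'
#' @param peaks `genomic_intervals` of candidate regions.
#' @param truth truth table from [simulate_activity_truth()] (one row per peak).
#' @param depth expected fragments per library (pre-contaminant), > 0.
#' @param n_input_reps,n_reps replicates for input and for each subset.
#' @param short_frac fraction of each RNA output that is short-fragment
#'   contaminant (default 0.3).
#' @param dispersion replicate-level overdispersion (gamma variance), default 0.05.
#' @param seed integer seed.
#' @return a `fragment_set` with samples named `input_<r>` and
#'   `<subset>_<r>`.
#' @export
simulate_starr_experiment <- function(peaks, truth, depth = 1e5,
                                      n_input_reps = 3L, n_reps = 3L,
                                      short_frac = 0.3, dispersion = 0.05,
                                      seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  stopifnot(nrow(truth) == nrow(peaks))
  set.seed(seed)
  subsets <- sub("^mult_", "", grep("^mult_", names(truth), value = TRUE))
  widths <- peaks$end - peaks$start
  base_rate <- widths / sum(widths)

  draw_library <- function(rate, sample_id, short) {
    lam <- depth * rate / sum(rate)
    if (dispersion > 0) {
      lam <- lam * stats::rgamma(length(lam), shape = 1 / dispersion,
                                 scale = dispersion)
    }
    n_per_peak <- stats::rpois(length(lam), lam)
    idx <- rep(seq_along(lam), n_per_peak)
    n <- length(idx)
    len <- .sim_main_lengths(n)
    if (short > 0 && n > 0) {
      n_short <- stats::rbinom(1L, n, short)
      if (n_short > 0) {
        si <- sample.int(n, n_short)
        len[si] <- .sim_short_lengths(n_short)
      }
    }
    fr <- .sim_place(peaks$chrom[idx], peaks$start[idx], peaks$end[idx], len)
    fr$sample <- sample_id
    fr
  }

  parts <- list()
  for (r in seq_len(n_input_reps)) {
    parts[[length(parts) + 1L]] <-
      draw_library(base_rate, sprintf("input_%d", r), short = 0)
  }
  for (s in subsets) {
    mult <- truth[[paste0("mult_", s)]]
    for (r in seq_len(n_reps)) {
      parts[[length(parts) + 1L]] <-
        draw_library(base_rate * mult, sprintf("%s_%d", s, r),
                     short = short_frac)
    }
  }
  all <- do.call(rbind, parts)
  fragment_set(all$chrom, all$start, all$end, all$sample)
}

.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#' @param x character string of A/C/G/T/N.
#' @return reverse complement string.
#' @export
revcomp <- function(x) {
  paste(rev(.DNA_COMP[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

#' Enumerate candidate SpCas9 guides (20-mers 5' of an NGG PAM)
#'
#' Scans both strands of the given regions for NGG protospacer-adjacent
#' motifs and reports every 20-mer immediately 5' of one, with its genomic
#' footprint (the 20 bp target, PAM excluded). Specificity scores are drawn
#' from a Beta distribution standing in for an external off-target scorer.
#'
#' @param sequence genome sequence (single string; coordinates are 0-based
#'   positions into it).
#' @param regions `genomic_intervals` within the sequence (chrom is taken
#'   from the regions and assumed to name this sequence).
#' @param seed integer seed for the specificity draws.
#' @param spec_shape1,spec_shape2 Beta parameters for specificity scores.
#' @return data.frame: region_id, chrom, start, end (20 bp footprint),
#'   strand, protospacer, specificity.
#' @export
simulate_guide_candidates <- function(sequence, regions, seed = 1L,
                                      spec_shape1 = 5, spec_shape2 = 2) {
  glen <- nchar(sequence)
  if (any(regions$end > glen)) stop("region outside sequence bounds")
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rs <- regions$start[i]; re <- regions$end[i]
    sub <- substr(sequence, rs + 1L, re)
    chars <- strsplit(sub, "", fixed = TRUE)[[1]]
    L <- length(chars)
    # plus strand: protospacer at p..p+19 (0-based in region), PAM p+20..p+22
    # with GG at p+21..p+22; require the full 23-mer inside the region
    plus <- which(chars[-L] == "G" & chars[-1] == "G")
    plus <- plus[plus >= 22L & plus + 1L <= L]  # GG at (plus, plus+1), 1-based
    plus_start0 <- plus - 22L                   # 0-based protospacer start
    # minus strand: CC at q..q+1 (1-based), protospacer rc of q+3..q+22
    minus <- which(chars[-L] == "C" & chars[-1] == "C")
    minus <- minus[minus + 22L <= L]
    for (k in seq_along(plus_start0)) {
      s0 <- plus_start0[k]
      out[[length(out) + 1L]] <- data.frame(
        region_id = i, chrom = regions$chrom[i],
        start = rs + s0, end = rs + s0 + 20L, strand = "+",
        protospacer = substr(sub, s0 + 1L, s0 + 20L),
        stringsAsFactors = FALSE)
    }
    for (k in seq_along(minus)) {
      q <- minus[k]
      out[[length(out) + 1L]] <- data.frame(
        region_id = i, chrom = regions$chrom[i],
        start = rs + q + 2L, end = rs + q + 22L, strand = "-",
        protospacer = revcomp(substr(sub, q + 3L, q + 22L)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(region_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protospacer = character(0),
                      specificity = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$region_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res$specificity <- stats::rbeta(nrow(res), spec_shape1, spec_shape2)
  res
}

#' Simulate sorted-bin screen counts with planted guide effects
#'
#' Negative-binomial (gamma-Poisson) counts for each guide in `hi` and `lo`
#' bins across replicates. The expected hi/lo ratio of a guide is
#' `2^effect` times the bin depth ratio; non-targeting controls have effect 0.
#'
#' @param guides character vector of guide ids.
#' @param effects per-guide log2 effect (same length/order as `guides`).
#' @param depth expected count per guide in the lo bin.
#' @param dispersion NB dispersion (0 gives Poisson).
#' @param n_reps replicate pairs.
#' @param bin_depth_ratio hi-bin depth relative to lo (default 1).
#' @param seed integer seed.
#' @return list: `counts` (guides x samples), `design` (sample, replicate,
#'   bin), `effects`.
#' @export
simulate_screen_counts <- function(guides, effects, depth = 500,
                                   dispersion = 0.05, n_reps = 3L,
                                   bin_depth_ratio = 1, seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  stopifnot(length(effects) == length(guides))
  set.seed(seed)
  ng <- length(guides)
  samples <- c(sprintf("lo_%d", seq_len(n_reps)),
               sprintf("hi_%d", seq_len(n_reps)))
  bins <- rep(c("lo", "hi"), each = n_reps)
  mu <- cbind(matrix(depth, ng, n_reps),
              matrix(depth * bin_depth_ratio * 2^effects, ng, n_reps))
  counts <- matrix(0L, ng, 2L * n_reps, dimnames = list(guides, samples))
  for (j in seq_len(ncol(mu))) {
    counts[, j] <- if (dispersion > 0) {
      stats::rnbinom(ng, mu = mu[, j], size = 1 / dispersion)
    } else {
      stats::rpois(ng, mu[, j])
    }
  }
  list(counts = counts,
       design = data.frame(sample = samples,
                           replicate = rep(seq_len(n_reps), 2L),
                           bin = bins, stringsAsFactors = FALSE),
       effects = stats::setNames(effects, guides))
}

#' Simulate a binned contact map with planted loops
#'
#' Expected counts follow a power-law distance decay
#' `(1 + |i - j|)^(-decay_exponent)`; loop pixels and their
#' `loop_spread`-bin neighborhood are multiplied by the loop enrichment;
#' upper-triangle counts are Poisson-sampled at the requested depth and
#' mirrored to keep the matrix symmetric. When an aggregate-window analysis
#' is meant to recover the planted enrichment exactly, plant the loop with
#' `loop_spread` equal to the analysis flank so the enriched footprint
#' coincides with the aggregation window.
#'
#' @param nbins matrix dimension.
#' @param resolution bin size in bp (metadata only).
#' @param decay_exponent power-law exponent (default 1).
#' @param loops data.frame with columns `i`, `j` (1-based bins) and
#'   `enrichment` (> 0); may be NULL.
#' @param depth expected total count over the upper triangle.
#' @param loop_spread neighborhood half-width (bins) over which the loop
#'   enrichment applies (default 1).
#' @param seed integer seed.
#' @return a `contact_matrix` (see [contact_matrix()]).
#' @export
simulate_contact_map <- function(nbins, resolution = 500L, decay_exponent = 1,
                                 loops = NULL, depth = 1e6,
                                 loop_spread = 1L, seed = 1L) {
  set.seed(seed)
  d <- abs(outer(seq_len(nbins), seq_len(nbins), "-"))
  ex <- (1 + d)^(-decay_exponent)
  if (!is.null(loops) && nrow(loops) > 0L) {
    if (any(loops$i > nbins | loops$j > nbins | loops$i < 1 | loops$j < 1)) {
      stop("loop coordinates outside matrix")
    }
    if (any(loops$enrichment <= 0)) stop("loop enrichment must be > 0")
    for (k in seq_len(nrow(loops))) {
      ii <- max(1L, loops$i[k] - loop_spread):min(nbins, loops$i[k] + loop_spread)
      jj <- max(1L, loops$j[k] - loop_spread):min(nbins, loops$j[k] + loop_spread)
      ex[ii, jj] <- ex[ii, jj] * loops$enrichment[k]
      ex[jj, ii] <- ex[jj, ii] * loops$enrichment[k]
      # symmetrize silently per the documented policy
    }
    ex[lower.tri(ex)] <- t(ex)[lower.tri(ex)]
  }
  up <- upper.tri(ex, diag = TRUE)
  lam <- ex[up] / sum(ex[up]) * depth
  counts <- matrix(0, nbins, nbins)
  counts[up] <- stats::rpois(length(lam), lam)
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, resolution = resolution)
}
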