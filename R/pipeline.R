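#' Run the full synthetic study end-to-end
#'
#' Exercises every stage on generated data with planted ground truth:
#' (1) genome, peaks and activity truth; (2) STARR-seq fragment simulation
#' and the sliding-window activity pipeline; (3) star-coordinate
#' specificity classification; (4) guide library design over a subset of
#' peaks; (5) a sorted-bin screen with planted guide effects; (6) paired
#' contact maps with a planted loop depletion, quantified by APA ratio.
#'
#' Scale defaults are deliberately desk-sized (minutes on one CPU).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_peaks number of candidate regions (default 300).
#' @param depth fragments per STARR library (default 2e5).
#' @param n_guide_regions regions carried into guide design (default 20).
#' @param screen_depth expected lo-bin count per guide (default 500).
#' @param contact_depth contact-map depth (default 1e6).
#' @param loop_depletion planted loop depletion factor (default 1.5).
#' @return list of per-stage results plus `recovery` summaries.
#' @export
run_synthetic_study <- function(seed = 1L, n_peaks = 300L, depth = 2e5,
                                n_guide_regions = 20L, screen_depth = 500,
                                contact_depth = 1e6, loop_depletion = 1.5) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, 8L)
  subsets <- c("Th0", "Th1", "Th2", "Th17", "Treg")

  # --- genome and peaks -----------------------------------------------
  peak_w <- 400L
  gap <- 1200L
  genome_len <- n_peaks * (peak_w + gap) + gap
  starts <- gap + (seq_len(n_peaks) - 1L) * (peak_w + gap)
  peaks <- genomic_intervals(rep("chrS", n_peaks), starts, starts + peak_w)

  truth <- simulate_activity_truth(n_peaks, subsets = subsets,
                                   seed = seeds[1])

  # --- STARR activity --------------------------------------------------
  frags <- simulate_starr_experiment(peaks, truth, depth = depth,
                                     seed = seeds[2])
  design <- data.frame(sample = sort(unique(frags$sample)),
                       stringsAsFactors = FALSE)
  design$group <- sub("_[0-9]+$", "", design$sample)
  design$group[grepl("^input", design$sample)] <- "input"
  starr <- starr_pipeline(frags, peaks, design)

  # map regions back to peaks (clusters overlap peaks 1:1 by construction)
  reg <- starr$regions
  peak_of <- find_overlaps_idx(
    genomic_intervals(reg$chrom, reg$start, reg$end), peaks)
  reg$peak <- NA_integer_
  reg$peak[peak_of$query] <- peak_of$subject
  starr$regions <- reg

  # --- specificity -----------------------------------------------------
  lfc <- matrix(NA_real_, n_peaks, length(subsets),
                dimnames = list(NULL, subsets))
  fdr <- matrix(1, n_peaks, length(subsets), dimnames = list(NULL, subsets))
  for (s in subsets) {
    rs <- reg[reg$subset == s & !is.na(reg$peak), , drop = FALSE]
    lfc[rs$peak, s] <- rs$rep_log2fc
    fdr[rs$peak, s] <- rs$fdr
  }
  lfc[is.na(lfc)] <- 0
  spec <- specificity_profile(lfc, fdr)

  # --- guide design ----------------------------------------------------
  gd_regions <- peaks[seq_len(n_guide_regions), , drop = FALSE]
  class(gd_regions) <- class(peaks)
  genome_seq <- simulate_genome(genome_len, gc = 0.45, seed = seeds[3])
  atac <- local({  # small ATAC fragment set over the design regions
    tr <- simulate_activity_truth(n_guide_regions, subsets = c("Th17", "Th0"),
                                  proportions = c(inactive = 1,
                                                  `shared-active` = 0,
                                                  `subset-specific` = 0,
                                                  repressive = 0),
                                  seed = seeds[4])
    fr <- simulate_starr_experiment(gd_regions, tr, depth = 5e4,
                                    n_input_reps = 0L, n_reps = 2L,
                                    short_frac = 0, seed = seeds[4])
    fragment_set(fr$chrom, fr$start, fr$end,
                 sample = sub("_[0-9]+$", "", fr$sample),
                 replicate = sub("^.*_", "", fr$sample))
  })
  lib <- design_guides(genome_seq, gd_regions, atac, cap = 10L,
                       seed = seeds[5])

  # --- screen ----------------------------------------------------------
  glib <- lib$library
  functional <- unique(glib$region_id[!glib$is_ntc])[
    seq_len(max(1L, floor(n_guide_regions / 4)))]
  effects <- ifelse(!glib$is_ntc & glib$region_id %in% functional, -2, 0)
  sim_scr <- simulate_screen_counts(glib$guide_id, effects,
                                    depth = screen_depth, seed = seeds[6])
  gres <- test_guides(sim_scr$counts, sim_scr$design)
  elements <- aggregate_elements(gres, glib)

  # --- contacts --------------------------------------------------------
  loops <- data.frame(i = c(60L, 60L), j = c(100L, 148L), enrichment = 3)
  ctrl <- ice_balance(simulate_contact_map(200L, decay_exponent = 1,
                                           loops = loops, loop_spread = 2L,
                                           depth = contact_depth,
                                           seed = seeds[7]))
  loops_dep <- transform(loops, enrichment = enrichment / loop_depletion)
  pert <- ice_balance(simulate_contact_map(200L, decay_exponent = 1,
                                           loops = loops_dep, loop_spread = 2L,
                                           depth = contact_depth,
                                           seed = seeds[8]))
  ar <- apa_ratio(observed_expected(ctrl), observed_expected(pert), loops)

  # --- recovery summaries ---------------------------------------------
  active_truth <- truth$class %in% c("shared-active", "subset-specific")
  called_active <- vapply(seq_len(n_peaks), function(p) {
    any(reg$class[!is.na(reg$peak) & reg$peak == p] == "active")
  }, logical(1))
  spec_truth <- truth[spec$region, , drop = FALSE]
  spec_ok <- spec_truth$class == "subset-specific"
  shared_ok <- spec_truth$class == "shared-active"
  recovery <- list(
    activity_sensitivity = mean(called_active[active_truth]),
    activity_fdr = if (any(called_active)) {
      mean(!active_truth[called_active])
    } else 0,
    specific_recovered = if (any(spec_ok)) {
      mean(spec$class[spec_ok] == "subset-preferred" &
             spec$dominant[spec_ok] == spec_truth$specific_subset[spec_ok])
    } else NA_real_,
    shared_recovered = if (any(shared_ok)) {
      mean(spec$class[shared_ok] == "shared")
    } else NA_real_,
    screen_sensitivity = with(elements$elements,
                              mean(significant[region_id %in% functional])),
    apa_ratio = mean(ar$ratio))
  list(truth = truth, peaks = peaks, starr = starr, specificity = spec,
       guides = lib, screen = list(results = gres, elements = elements),
       contacts = list(ratio = ar), recovery = recovery, seed = seed)
}
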