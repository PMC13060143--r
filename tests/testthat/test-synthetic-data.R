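test_that("simulate_genome hits the requested GC and is reproducible", {
  g <- simulate_genome(1e5, gc = 0.5, seed = 3)
  gc_obs <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 0.01)
  expect_identical(g, simulate_genome(1e5, gc = 0.5, seed = 3))
  expect_false(identical(g, simulate_genome(1e5, gc = 0.5, seed = 4)))
  expect_error(simulate_genome(0, 0.5), "length")
  expect_error(simulate_genome(10, 0), "gc")
})

test_that("activity truth respects class definitions", {
  tr <- simulate_activity_truth(500, seed = 5)
  mult <- as.matrix(tr[, grep("^mult_", names(tr))])
  spec <- tr$class == "subset-specific"
  expect_true(all(rowSums(mult[spec, , drop = FALSE] > 1) == 1))
  expect_true(all(mult[tr$class == "shared-active", ] > 1))
  expect_true(all(mult[tr$class == "inactive", ] == 1))
  expect_true(all(mult[tr$class == "repressive", ] < 1))
})

test_that("null STARR simulation gives unit output/input CPM ratio", {
  peaks <- even_peaks(50)
  tr <- simulate_activity_truth(50, proportions = c(
    inactive = 1, `shared-active` = 0, `subset-specific` = 0, repressive = 0))
  fr <- simulate_starr_experiment(peaks, tr, depth = 1e6, n_reps = 1L,
                                  n_input_reps = 1L, short_frac = 0,
                                  dispersion = 0, seed = 8)
  fr <- filter_fragments(fr)
  cnt <- sapply(c("input_1", "Th17_1"), function(s) {
    count_overlaps_bp(peaks, fr[fr$sample == s, , drop = FALSE])
  })
  cpm <- cpm_normalize(cnt)
  expect_lt(abs(mean(log2(cpm[, 2] / cpm[, 1]))), 0.05)
})

test_that("planted 4-fold peak shows a ~4x post-filter ratio", {
  peaks <- even_peaks(50)
  tr <- simulate_activity_truth(50, proportions = c(
    inactive = 1, `shared-active` = 0, `subset-specific` = 0, repressive = 0))
  tr$mult_Th17[1] <- 4
  fr <- simulate_starr_experiment(peaks, tr, depth = 5e5, n_reps = 1L,
                                  n_input_reps = 1L, short_frac = 0,
                                  dispersion = 0, seed = 9)
  fr <- filter_fragments(fr)
  cnt <- sapply(c("input_1", "Th17_1"), function(s) {
    count_overlaps_bp(peaks, fr[fr$sample == s, , drop = FALSE])
  })
  cpm <- cpm_normalize(cnt)
  ratio <- cpm[, 2] / cpm[, 1]
  null_ratio <- mean(ratio[-1])
  # Poisson sampling error at ~1e4 counts/peak is ~2%; allow 4 sd
  expect_lt(abs(ratio[1] / null_ratio - 4), 4 * 4 * sqrt(4 / 9000))
})

test_that("short-fragment contaminant lands only in outputs", {
  peaks <- even_peaks(20)
  tr <- simulate_activity_truth(20)
  fr <- simulate_starr_experiment(peaks, tr, depth = 2e4, short_frac = 0.3,
                                  seed = 10)
  len <- fr$end - fr$start
  out_short <- mean(len[!grepl("^input", fr$sample)] < 140)
  in_short <- mean(len[grepl("^input", fr$sample)] < 140)
  expect_gte(out_short, 0.25)
  expect_equal(in_short, 0)
  # determinism
  fr2 <- simulate_starr_experiment(peaks, tr, depth = 2e4, short_frac = 0.3,
                                   seed = 10)
  expect_identical(fr, fr2)
})

test_that("guide candidate enumeration matches brute-force PAM scan", {
  # every NGG on either strand with the full 23-mer inside yields one guide
  seq <- "AAAAACCGGTTAAAAACCGGTTAAAAACCGGTT"
  r <- genomic_intervals("g", 0, nchar(seq))
  cand <- simulate_guide_candidates(seq, r)
  expect_equal(nrow(cand), brute_pam_scan(seq))

  expect_equal(nrow(simulate_guide_candidates(strrep("A", 200),
                                              genomic_intervals("g", 0, 200))),
               0L)

  set.seed(13)
  for (i in 1:10) {
    g <- simulate_genome(200, gc = 0.5, seed = 100 + i)
    cand <- simulate_guide_candidates(g, genomic_intervals("g", 0, 200))
    expect_equal(nrow(cand), brute_pam_scan(g))
    # protospacer matches the genome at its footprint, strand-aware
    for (k in seq_len(min(nrow(cand), 5))) {
      sub <- substr(g, cand$start[k] + 1, cand$end[k])
      exp <- if (cand$strand[k] == "+") sub else revcomp(sub)
      expect_identical(cand$protospacer[k], exp)
    }
  }
})

test_that("screen counts have the planted mean structure", {
  ids <- sprintf("g%d", 1:400)
  # dispersion 0 -> Poisson: variance/mean ~ 1 across null guides
  sim <- simulate_screen_counts(ids, rep(0, 400), depth = 500,
                                dispersion = 0, seed = 6)
  vm <- apply(sim$counts, 1, var) / rowMeans(sim$counts)
  expect_lt(abs(mean(vm) - 1), 0.15)
  # planted effect -2: normalized hi/lo ratio ~ 0.25
  eff <- c(rep(-2, 40), rep(0, 360))
  sim2 <- simulate_screen_counts(ids, eff, depth = 500, seed = 7)
  hi <- rowMeans(sim2$counts[, sim2$design$bin == "hi"])
  lo <- rowMeans(sim2$counts[, sim2$design$bin == "lo"])
  expect_lt(abs(mean(hi[1:40] / lo[1:40]) - 0.25), 0.04)
  expect_lt(abs(mean(log2(hi[41:400] / lo[41:400]))), 0.05)
  expect_error(simulate_screen_counts(ids, eff, depth = -1), "depth")
})

test_that("contact map simulation is symmetric, reproducible, null-flat", {
  cm <- simulate_contact_map(120, loops = NULL, depth = 1e6, seed = 4)
  expect_identical(cm$counts, t(cm$counts))
  cm2 <- simulate_contact_map(120, loops = NULL, depth = 1e6, seed = 4)
  expect_identical(cm$counts, cm2$counts)
  oe <- observed_expected(ice_balance(cm))$oe
  d <- abs(row(oe) - col(oe))
  diag_means <- vapply(0:60, function(k) mean(oe[d == k], na.rm = TRUE),
                       numeric(1))
  expect_lt(max(abs(diag_means - 1)), 0.05)
  expect_error(simulate_contact_map(10, loops = data.frame(
    i = 20, j = 2, enrichment = 3)), "outside")
})
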