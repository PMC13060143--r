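test_that("fragment length filter is inclusive on both bounds", {
  fr <- fragment_set("c", c(0, 0, 0, 0, 0), c(100, 150, 500, 800, 900), "s")
  out <- filter_fragments(fr)
  expect_equal(out$end - out$start, c(150L, 500L, 800L))
  expect_equal(nrow(filter_fragments(fr[0, ])), 0L)
  all_in <- fragment_set("c", c(0, 10), c(200, 310), "s")
  expect_equal(nrow(filter_fragments(all_in)), 2L)
  expect_error(filter_fragments(fr, 800, 150), "min_len")
})

test_that("window tiling anchors at step multiples and respects peaks", {
  w <- make_windows(genomic_intervals("chr1", 1000, 1100))
  expect_equal(w$start, c(975L, 1000L, 1025L, 1050L, 1075L))
  expect_equal(w$end - w$start, rep(50L, 5))
  expect_equal(nrow(make_windows(genomic_intervals(character(0), integer(0),
                                                   integer(0)))), 0L)
  # peak narrower than the step still yields windows
  expect_gte(nrow(make_windows(genomic_intervals("c", 1003, 1013))), 1L)
  # every returned window overlaps a peak; none outside
  set.seed(3)
  st <- sort(sample.int(1e5, 20))
  peaks <- genomic_intervals(rep("c", 20), st, st + sample(30:600, 20, TRUE))
  win <- make_windows(peaks)
  expect_true(all(count_overlaps_bp(win, peaks) >= 1))
  expect_true(all(win$start %% 25 == 0))
})

test_that("window counting matches the quadratic oracle", {
  win <- genomic_intervals(rep("c", 2), c(0, 25), c(50, 75))
  fr <- fragment_set("c", 0, 300, "s")
  expect_equal(as.vector(count_in_windows(fr, win)), c(1L, 1L))

  set.seed(21)
  st <- sample.int(5000, 100)
  fr <- fragment_set("c", st, st + sample(150:400, 100, TRUE),
                     sample(c("a", "b"), 100, TRUE))
  wst <- sample.int(5000, 50)
  win <- genomic_intervals(rep("c", 50), wst, wst + 50L)
  got <- count_in_windows(fr, win, samples = c("a", "b"))
  for (s in c("a", "b")) {
    expect_equal(got[, s],
                 brute_count_overlaps(win, fr[fr$sample == s, ]))
  }
  expect_equal(sum(count_in_windows(fr[0, ], win)), 0L)
})

test_that("identical RNA and input counts give exactly zero log2FC", {
  counts <- matrix(rep(c(5L, 9L, 14L, 0L, 3L), 4), ncol = 4)
  colnames(counts) <- c("input_1", "input_2", "Th17_1", "Th17_2")
  design <- data.frame(sample = colnames(counts),
                       group = c("input", "input", "Th17", "Th17"))
  ws <- test_windows(counts, design,
                     lib_sizes = setNames(rep(100L, 4), colnames(counts)))
  expect_equal(ws$log2fc, rep(0, nrow(ws)), tolerance = 1e-8)
  expect_equal(attr(ws, "n_excluded"), 1L)
})

test_that("window test recovers planted fold changes at depth 200", {
  # direct window-level count simulation: 300 null + 100 at 4-fold
  set.seed(31)
  n <- 400
  mu <- 200
  mult <- c(rep(1, 300), rep(4, 100))
  samples <- c(paste0("input_", 1:3), paste0("Th17_", 1:3))
  counts <- cbind(
    matrix(rnbinom(n * 3, mu = mu, size = 20), n, 3),
    matrix(rnbinom(n * 3, mu = 2 * mu * mult, size = 20), n, 3))
  colnames(counts) <- samples
  design <- data.frame(sample = samples,
                       group = rep(c("input", "Th17"), each = 3))
  # RNA libraries sequenced twice as deep: offsets must absorb it
  libs <- setNames(rep(1e6, 6) * c(1, 1, 1, 2, 2, 2), samples)
  ws <- test_windows(counts, design, lib_sizes = libs)
  expect_lt(abs(mean(ws$log2fc[ws$window > 300]) - 2), 0.15)
  expect_lt(abs(mean(ws$log2fc[ws$window <= 300])), 0.1)
})

test_that("window merging chains by gap and splits wide chains", {
  w1 <- genomic_intervals(rep("c", 2), c(100, 125), c(150, 175))
  m1 <- merge_windows(w1)
  expect_equal(max(m1$cluster), 1L)
  expect_equal(c(m1$regions$start, m1$regions$end), c(100L, 175L))

  w2 <- genomic_intervals(rep("c", 2), c(100, 151), c(150, 201))
  expect_equal(max(merge_windows(w2, tolerance = 0)$cluster), 2L)
  expect_equal(max(merge_windows(w2, tolerance = 1)$cluster), 1L)

  # 200 abutting 50-bp windows spanning 5,025 bp -> 2 clusters <= 3,000 bp
  st <- (0:199) * 25L
  w3 <- genomic_intervals(rep("c", 200), st, st + 50L)
  m3 <- merge_windows(w3, tolerance = 0, max_width = 3000)
  expect_equal(max(m3$cluster), 2L)
  expect_true(all(m3$regions$end - m3$regions$start <= 3000))
  # near-equal member counts
  expect_equal(sort(as.integer(table(m3$cluster))), c(100L, 100L))
})

test_that("region p combination reproduces hand-computed Holm examples", {
  cc <- combine_region_pvalues(c(0.001, 0.01, 0.2), c(1, -2, 3),
                               min_sig_n = 3)
  expect_equal(cc$p, 0.2)
  expect_equal(cc$rep_log2fc, 1)  # smallest adjusted p is window 1
  single <- combine_region_pvalues(0.03, 1.5, min_sig_n = 3)
  expect_equal(single$p, 0.03)
  expect_equal(single$k, 1L)
})

test_that("weighted Holm matches the brute-force oracle", {
  set.seed(41)
  for (i in 1:500) {
    n <- sample(2:8, 1)
    p <- runif(n)
    w <- sample(c(1, 1, 1, 4), n, TRUE)
    expect_equal(weighted_holm(p, w), brute_weighted_holm(p, w))
  }
})

test_that("combined p never undercuts the smallest member p", {
  set.seed(43)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    p <- runif(n)
    ab <- runif(n)
    cc <- combine_region_pvalues(p, rnorm(n), abundance = ab)
    expect_gte(cc$p, min(p))
    expect_lte(cc$p, 1)
  }
})

test_that("region classification applies BH and sign rules", {
  reg <- data.frame(combined_p = c(0.01, 0.02, 0.03, 0.04),
                    rep_log2fc = c(2, -1, 0.5, 3))
  out <- classify_regions(reg)
  expect_equal(out$fdr, rep(0.04, 4))
  expect_equal(out$class, c("active", "repressive", "active", "active"))
  reg1 <- data.frame(combined_p = rep(1, 5), rep_log2fc = rnorm(5))
  expect_true(all(classify_regions(reg1)$class == "not-significant"))
})

test_that("pipeline output is invariant to sample order and global depth", {
  peaks <- even_peaks(15)
  tr <- simulate_activity_truth(15, seed = 2)
  fr <- simulate_starr_experiment(peaks, tr, depth = 3e4, seed = 12)
  design <- starr_design(fr)
  r1 <- starr_pipeline(fr, peaks, design, tmm = FALSE)
  r2 <- starr_pipeline(fr, peaks, design[rev(seq_len(nrow(design))), ],
                       tmm = FALSE)
  m1 <- r1$regions[order(r1$regions$region, r1$regions$subset), ]
  m2 <- r2$regions[order(r2$regions$region, r2$regions$subset), ]
  expect_equal(m1$combined_p, m2$combined_p, tolerance = 1e-9)
  expect_equal(m1$rep_log2fc, m2$rep_log2fc, tolerance = 1e-9)
  # doubling every library leaves log2FC unchanged (counts scale together)
  fr2 <- rbind(fr, fr)
  class(fr2) <- class(fr)
  r3 <- starr_pipeline(fr2, peaks, design, tmm = FALSE)
  expect_equal(r3$regions$rep_log2fc[order(r3$regions$region,
                                           r3$regions$subset)],
               m1$rep_log2fc, tolerance = 0.02)
})
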