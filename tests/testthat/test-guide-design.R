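test_that("candidate filtering enforces score threshold and banned repeats", {
  cand <- data.frame(
    protospacer = c("ACGTACGTACGTACGTACGA", "ACGTACGTACGTACGTTTTA",
                    "ACGGGGGCGTACGTACGACG", "ACGTACGTACGTACGTACGC"),
    specificity = c(0.15, 0.9, 0.9, 0.2))
  out <- filter_candidates(cand)
  # 1 fails score; 2 contains TTTT; 3 contains GGGGG; 4 kept at the boundary
  expect_equal(out$protospacer, "ACGTACGTACGTACGTACGC")
})

test_that("accessibility score is max over subset means of replicate CPM", {
  cand <- data.frame(chrom = "c", start = 100L, end = 120L)
  # subset A: replicate CPM-sums (3, 1) -> mean 2; subset B: (1, 1) -> mean 1
  mk <- function(n_over, n_total, sample, rep) {
    st <- c(rep(90L, n_over), rep(5000L, n_total - n_over))
    fragment_set("c", st, st + 50L, sample, rep)
  }
  fr <- rbind(mk(3, 1e6, "A", 1), mk(1, 1e6, "A", 2),
              mk(1, 1e6, "B", 1), mk(1, 1e6, "B", 2))
  class(fr) <- c("fragment_set", "data.frame")
  expect_equal(accessibility_score(cand, fr), 2)
  # no overlap anywhere -> 0
  cand0 <- data.frame(chrom = "c", start = 9e6, end = 9e6 + 20)
  expect_equal(accessibility_score(cand0, fr), 0)
})

test_that("accessibility matches a quadratic oracle on random fragments", {
  set.seed(61)
  st <- sample.int(20000, 1000)
  fr <- fragment_set("c", st, st + sample(100:300, 1000, TRUE),
                     sample = "Th17", replicate = sample(1:2, 1000, TRUE))
  cs <- sample.int(20000, 30)
  cand <- data.frame(chrom = "c", start = cs, end = cs + 20L)
  got <- accessibility_score(cand, fr)
  want <- sapply(seq_len(30), function(i) {
    mean(sapply(1:2, function(r) {
      sub <- fr[fr$replicate == r, ]
      brute_count_overlaps(cand[i, , drop = FALSE], sub) * 1e6 / nrow(sub)
    }))
  })
  expect_equal(got, want)
})

test_that("greedy selection follows the documented hand trace", {
  cand <- data.frame(start = c(0L, 5L, 15L, 40L),
                     end = c(20L, 25L, 35L, 60L),
                     protospacer = c("A", "B", "C", "D"),
                     accessibility = c(10, 9, 8, 7))
  out <- select_guides(cand)
  expect_equal(out$start, c(0L, 15L, 40L))
  expect_equal(out$rank_in_peak, 1:3)
  one <- select_guides(cand[2, , drop = FALSE])
  expect_equal(nrow(one), 1L)
})

test_that("greedy selection equals brute-force replay with tied scores", {
  set.seed(62)
  for (i in 1:300) {
    n <- sample(1:12, 1)
    st <- sample.int(80, n)
    cand <- data.frame(start = st, end = st + 20L,
                       protospacer = replicate(n, paste(
                         sample(c("A", "C", "G", "T"), 20, TRUE),
                         collapse = "")),
                       score = sample(1:4, n, TRUE))  # heavy ties
    cand$accessibility <- cand$score
    cap <- sample(1:12, 1)
    got <- select_guides(cand, cap = cap, max_overlap = 10L)
    want <- brute_greedy_select(cand, cap = cap, max_overlap = 10L)
    expect_equal(got$start, cand$start[want])
    # invariant: no selected pair overlaps by more than 10 bp
    if (nrow(got) > 1) {
      for (a in 1:(nrow(got) - 1)) for (b in (a + 1):nrow(got)) {
        ov <- max(0, min(got$end[a], got$end[b]) -
                    max(got$start[a], got$start[b]))
        expect_lte(ov, 10)
      }
    }
  }
})

test_that("raising the cap preserves the greedy prefix", {
  set.seed(63)
  st <- sample.int(200, 30)
  cand <- data.frame(start = st, end = st + 20L,
                     protospacer = sprintf("P%02d", 1:30),
                     accessibility = runif(30))
  s5 <- select_guides(cand, cap = 5L)
  s10 <- select_guides(cand, cap = 10L)
  expect_equal(s10$start[1:nrow(s5)], s5$start)
})

test_that("NTC guides are GC-matched and absent from the genome", {
  set.seed(64)
  genome <- simulate_genome(1e5, gc = 0.45, seed = 65)
  targeting <- replicate(300, paste(sample(c("A", "C", "G", "T"), 20, TRUE,
                                           prob = c(.3, .2, .2, .3)),
                                    collapse = ""))
  ntc <- generate_ntc(targeting, 200L, genome, seed = 66)
  expect_equal(length(ntc), 200L)
  # GC-count distributions close in total variation
  tv <- function(a, b) {
    lv <- 0:20
    sum(abs(tabulate(factor(a, lv), 21) / length(a) -
              tabulate(factor(b, lv), 21) / length(b))) / 2
  }
  gc_t <- sapply(strsplit(targeting, ""), function(x) sum(x %in% c("G", "C")))
  gc_n <- sapply(strsplit(ntc, ""), function(x) sum(x %in% c("G", "C")))
  expect_lte(tv(gc_t, gc_n), 0.12)
  # zero hits (exact or 1-mismatch, either strand) against the genome
  gd <- Biostrings::DNAString(genome)
  hits <- sapply(ntc[1:50], function(s) {
    p <- Biostrings::DNAString(s)
    Biostrings::countPattern(p, gd, max.mismatch = 1) +
      Biostrings::countPattern(Biostrings::reverseComplement(p), gd,
                               max.mismatch = 1)
  })
  expect_true(all(hits == 0))
})

test_that("library assembly sizes NTCs as a share of the final total", {
  set.seed(67)
  sel <- data.frame(region_id = rep(1:10, each = 10), chrom = "c",
                    start = seq_len(100) * 30L,
                    end = seq_len(100) * 30L + 20L, strand = "+",
                    protospacer = replicate(100, paste(
                      sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")),
                    specificity = runif(100, 0.3, 1),
                    accessibility = runif(100),
                    rank_in_peak = rep(1:10, 10))
  genome <- simulate_genome(2e4, gc = 0.5, seed = 68)
  lib <- assemble_library(sel, genome, ntc_fraction = 0.05)
  # 100 targeting -> 5 NTCs (100/0.95 * 0.05 ~ 5.26, rounded)
  expect_equal(lib$summary$n_ntc, 5L)
  expect_lt(abs(lib$summary$ntc_fraction - 0.05), 0.01)
  expect_equal(nrow(lib$library), 105L)
  expect_error(assemble_library(sel[0, ], genome), "no targeting")
  # duplicate protospacers collapse with a warning
  sel2 <- sel; sel2$protospacer[2] <- sel2$protospacer[1]
  expect_warning(lib2 <- assemble_library(sel2, genome), "duplicate")
  expect_equal(sum(!lib2$library$is_ntc), 99L)
})
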