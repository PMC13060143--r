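# Independent brute-force oracles used across tests. These deliberately
# re-derive results from definitions (quadratic scans, exhaustive replay)
# rather than calling the package's own implementations.

# all-pairs overlap counting: intervals are data.frames with chrom/start/end
brute_count_overlaps <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    sum(vapply(seq_len(nrow(subject)), function(j) {
      query$chrom[i] == subject$chrom[j] &&
        min(query$end[i], subject$end[j]) -
          max(query$start[i], subject$start[j]) > 0
    }, logical(1)))
  }, integer(1))
}

# weighted Holm by direct definition: visit hypotheses in increasing p/w,
# multiply by remaining weight over own weight, running max, cap at 1
brute_weighted_holm <- function(p, w) {
  n <- length(p)
  ord <- order(p / w)
  adj <- numeric(n)
  run <- 0
  left <- sum(w)
  for (i in ord) {
    adj[i] <- max(run, min(1, p[i] * left / w[i]))
    run <- adj[i]
    left <- left - w[i]
  }
  adj
}

# greedy guide selection replayed literally from the rule text
brute_greedy_select <- function(cand, cap, max_overlap) {
  ord <- order(-cand$score, cand$start, cand$protospacer)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= cap) break
    ok <- TRUE
    for (s in sel) {
      ov <- max(0, min(cand$end[s], cand$end[i]) -
                  max(cand$start[s], cand$start[i]))
      if (ov > max_overlap) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, i)
  }
  sel
}

# brute-force NGG PAM enumeration on a plain string (both strands)
brute_pam_scan <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  hits <- 0L
  for (t in seq_len(n)) {           # plus strand protospacer start (1-based)
    if (t + 22 <= n && ch[t + 20 + 1] == "G" && ch[t + 21 + 1] == "G") {
      hits <- hits + 1L
    }
  }
  for (q in seq_len(n)) {           # minus strand: CCN then 20-mer
    if (q + 22 <= n && ch[q] == "C" && ch[q + 1] == "C") hits <- hits + 1L
  }
  hits
}

# deterministic seeded design table for a 5-subset STARR run
starr_design <- function(fragments) {
  d <- data.frame(sample = sort(unique(fragments$sample)),
                  stringsAsFactors = FALSE)
  d$group <- sub("_[0-9]+$", "", d$sample)
  d$group[grepl("^input", d$sample)] <- "input"
  d
}

# evenly spaced peaks on one synthetic chromosome
even_peaks <- function(n, width = 400L, gap = 1200L) {
  starts <- gap + (seq_len(n) - 1L) * (width + gap)
  genomic_intervals(rep("chrS", n), starts, starts + width)
}
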