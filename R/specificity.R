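#' Per-subset weighted effect scores
#'
#' Combines magnitude and confidence of subset activity:
#' `w_i = |log2FC_i| * (-log10 FDR_i)`, with FDR floored at 1e-300 before
#' the log. Regions with no subset passing the significance filter are
#' dropped.
#'
#' @param log2fc matrix regions x subsets of log2 fold changes.
#' @param fdr matrix regions x subsets of BH FDR values in (0, 1].
#' @param sig_filter keep regions with FDR < this in >= 1 subset (default 0.01).
#' @return list: `weights` (matrix for retained regions), `kept` (original
#'   row indices).
#' @export
weighted_scores <- function(log2fc, fdr, sig_filter = 0.01) {
  log2fc <- as.matrix(log2fc); fdr <- as.matrix(fdr)
  stopifnot(all(dim(log2fc) == dim(fdr)))
  keep <- rowSums(fdr < sig_filter, na.rm = TRUE) >= 1L
  w <- abs(log2fc) * (-log10(pmax(fdr, 1e-300)))
  w[is.na(w)] <- 0
  list(weights = w[keep, , drop = FALSE], kept = which(keep))
}

#' Normalize weights to proportional shares
#'
#' `s_i = w_i / sum(w)` per region. Regions whose weights are all zero are
#' degenerate (no direction information) and are excluded rather than
#' mapped to the origin.
#'
#' @param weights matrix regions x subsets of raw weights, >= 0.
#' @return list: `shares` (rows sum to 1), `kept` (row indices of the
#'   input that were retained), `n_degenerate`.
#' @export
normalize_shares <- function(weights) {
  weights <- as.matrix(weights)
  tot <- rowSums(weights)
  keep <- tot > 0
  s <- sweep(weights[keep, , drop = FALSE], 1L, tot[keep], "/")
  list(shares = s, kept = which(keep), n_degenerate = sum(!keep))
}

#' Star-coordinate projection of share vectors
#'
#' Each subset gets an equally spaced spoke angle `theta_i = 2 pi i / n`
#' (i = 0..n-1); a region's position is the share-weighted vector sum
#' `x = sum(s_i cos theta_i)`, `y = sum(s_i sin theta_i)`. Regions active
#' in a single subset land exactly on that spoke with radius 1; uniform
#' activity lands at the origin.
#'
#' @param shares matrix regions x subsets, rows summing to 1.
#' @return data.frame: x, y, r, angle (atan2 of the position).
#' @export
star_project <- function(shares) {
  shares <- as.matrix(shares)
  n <- ncol(shares)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  x <- as.numeric(shares %*% cos(theta))
  y <- as.numeric(shares %*% sin(theta))
  data.frame(x = x, y = y, r = sqrt(x^2 + y^2), angle = atan2(y, x))
}

# absolute circular difference between two angles, in [0, pi]
.circ_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Classify regions as subset-preferred, shared, or intermediate
#'
#' Subset-preferred regions are those with radius above `r_specific`; within
#' each dominant subset they are ranked by angular proximity of their
#' position to the subset's spoke and capped at `cap_specific`. Shared
#' regions have radius below `r_shared`, capped at `cap_shared` (smallest
#' radii first). Everything else is intermediate. The dominant subset is
#' the argmax of the raw weights (ties to the lowest subset index).
#'
#' @param weights raw weight matrix (regions x subsets).
#' @param shares matching share matrix.
#' @param r_specific,r_shared radius thresholds (defaults 0.85, 0.10).
#' @param cap_specific per-subset cap on selected specific regions (2000).
#' @param cap_shared cap on selected shared regions (5000).
#' @return data.frame: x, y, r, dominant, class, selected (logical: in the
#'   capped specific/shared selection).
#' @export
classify_specificity <- function(weights, shares, r_specific = 0.85,
                                 r_shared = 0.10, cap_specific = 2000L,
                                 cap_shared = 5000L) {
  stopifnot(r_shared < r_specific)
  subsets <- colnames(weights)
  if (is.null(subsets)) subsets <- paste0("S", seq_len(ncol(weights)))
  proj <- star_project(shares)
  dom_idx <- apply(weights, 1L, which.max)
  proj$dominant <- subsets[dom_idx]
  n <- ncol(weights)
  spoke <- 2 * pi * (seq_len(n) - 1L) / n

  proj$class <- "intermediate"
  proj$class[proj$r > r_specific] <- "subset-preferred"
  proj$class[proj$r < r_shared] <- "shared"

  proj$selected <- FALSE
  for (k in seq_len(n)) {
    idx <- which(proj$class == "subset-preferred" & dom_idx == k)
    if (length(idx) == 0L) next
    dev <- .circ_diff(proj$angle[idx], spoke[k])
    take <- idx[order(dev)][seq_len(min(cap_specific, length(idx)))]
    proj$selected[take] <- TRUE
  }
  sh <- which(proj$class == "shared")
  if (length(sh) > 0L) {
    take <- sh[order(proj$r[sh])][seq_len(min(cap_shared, length(sh)))]
    proj$selected[take] <- TRUE
  }
  proj
}

#' Motif-family enrichment between a selected set and background
#'
#' Per motif family, a 2x2 table of (selected vs background) x (hit vs
#' no-hit), a two-sided Fisher exact p-value, an odds ratio (with the
#' Haldane-Anscombe 0.5 continuity correction when any cell is zero), and
#' BH adjustment across families.
#'
#' @param selected logical vector (or indices) marking the selected regions.
#' @param annotations binary matrix regions x families.
#' @return data.frame: family, a, b, c, d, odds_ratio, p, fdr.
#' @export
motif_family_enrichment <- function(selected, annotations) {
  annotations <- as.matrix(annotations)
  if (is.logical(selected)) {
    sel <- selected
  } else {
    sel <- rep(FALSE, nrow(annotations)); sel[selected] <- TRUE
  }
  if (!any(sel)) stop("selected set is empty")
  fams <- colnames(annotations)
  if (is.null(fams)) fams <- paste0("family", seq_len(ncol(annotations)))
  res <- lapply(seq_len(ncol(annotations)), function(j) {
    hit <- annotations[, j] > 0
    a <- sum(sel & hit); b <- sum(sel & !hit)
    cc <- sum(!sel & hit); d <- sum(!sel & !hit)
    or <- if (any(c(a, b, cc, d) == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * d) / (b * cc)
    }
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))$p.value
    data.frame(family = fams[j], a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Full specificity profile from per-subset activity tables
#'
#' Convenience wrapper: weighted scores, share normalization, star
#' projection, and classification in one call.
#'
#' @inheritParams weighted_scores
#' @inheritParams classify_specificity
#' @return data.frame with one row per retained region: original row index
#'   (`region`), weights, shares, x, y, r, dominant, class, selected.
#' @export
specificity_profile <- function(log2fc, fdr, sig_filter = 0.01,
                                r_specific = 0.85, r_shared = 0.10,
                                cap_specific = 2000L, cap_shared = 5000L) {
  ws <- weighted_scores(log2fc, fdr, sig_filter)
  ns <- normalize_shares(ws$weights)
  w <- ws$weights[ns$kept, , drop = FALSE]
  cls <- classify_specificity(w, ns$shares, r_specific, r_shared,
                              cap_specific, cap_shared)
  cbind(data.frame(region = ws$kept[ns$kept]), cls)
}
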