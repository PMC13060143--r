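#' Construct a contact matrix
#'
#' Binned symmetric contact counts over a captured locus, with optional
#' balancing weights (filled by [ice_balance()]).
#'
#' @param counts symmetric non-negative numeric matrix.
#' @param resolution bin size in bp.
#' @param chrom,offset locus location metadata (bin 1 starts at `offset`).
#' @return list with class `contact_matrix`: counts, resolution, chrom,
#'   offset, weights (NULL until balanced), mask.
#' @export
contact_matrix <- function(counts, resolution = 500L, chrom = "locus",
                           offset = 0L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("contact matrix must be square")
  if (max(abs(counts - t(counts))) > 1e-8) {
    stop("contact matrix must be symmetric")
  }
  if (any(counts < 0)) stop("contact counts must be non-negative")
  structure(list(counts = counts, resolution = as.integer(resolution),
                 chrom = chrom, offset = as.integer(offset),
                 weights = NULL, mask = rep(FALSE, nrow(counts))),
            class = "contact_matrix")
}

#' Write a contact matrix as COO text with a JSON sidecar
#'
#' Upper-triangle nonzero pixels as `bin_i bin_j count` (1-based, TSV);
#' resolution/chrom/offset/nbins go to `<path>.json`.
#'
#' @param cm `contact_matrix`.
#' @param path output path for the COO table.
#' @export
write_coo <- function(cm, path) {
  up <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
              arr.ind = TRUE)
  df <- data.frame(bin_i = up[, 1], bin_j = up[, 2],
                   count = cm$counts[up])
  df <- df[order(df$bin_i, df$bin_j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- list(nbins = nrow(cm$counts), resolution = cm$resolution,
               chrom = cm$chrom, offset = cm$offset)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a contact matrix from COO text
#'
#' @param path COO table written by [write_coo()] (JSON sidecar required).
#' @return `contact_matrix`.
#' @export
read_coo <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- matrix(0, meta$nbins, meta$nbins)
  m[cbind(df$bin_i, df$bin_j)] <- df$count
  m[cbind(df$bin_j, df$bin_i)] <- df$count
  contact_matrix(m, resolution = meta$resolution, chrom = meta$chrom,
                 offset = meta$offset)
}

#' Iterative correction (ICE) balancing
#'
#' Iterative proportional fitting of per-bin weights so that the balanced
#' matrix `diag(w) M diag(w)` has equal marginals. Bins whose raw marginal
#' count is below `min_count` are masked and excluded throughout. Weights
#' are rescaled so the mean non-masked balanced marginal is 1.
#'
#' @param cm `contact_matrix`.
#' @param max_iter iteration cap (default 500).
#' @param tol convergence tolerance on the coefficient of variation of the
#'   non-masked marginals (default 1e-6).
#' @param min_count marginal threshold for masking (default 1).
#' @return `contact_matrix` with `weights`, `mask`, and `balanced` filled;
#'   attribute `converged` and `cv` record the outcome.
#' @export
ice_balance <- function(cm, max_iter = 500L, tol = 1e-6, min_count = 1) {
  m <- cm$counts
  n <- nrow(m)
  mask <- rowSums(m) < min_count | rowSums(m) == 0
  w <- rep(1, n)
  w[mask] <- 0
  cv <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    marg <- as.numeric((m %*% w) * w)
    act <- marg[!mask]
    cv <- stats::sd(act) / mean(act)
    if (is.finite(cv) && cv < tol) { converged <- TRUE; break }
    upd <- marg
    upd[!mask] <- marg[!mask] / mean(marg[!mask])
    w[!mask] <- w[!mask] / sqrt(upd[!mask])
  }
  # rescale: mean non-masked balanced marginal = 1
  marg <- as.numeric((m %*% w) * w)
  s <- mean(marg[!mask])
  if (s > 0) w <- w / sqrt(s)
  if (!converged) {
    warning(sprintf("ICE did not converge: final marginal CV %.3g", cv))
  }
  cm$weights <- w
  cm$mask <- mask
  cm$balanced <- outer(w, w) * m
  attr(cm, "converged") <- converged
  attr(cm, "cv") <- cv
  cm
}

#' Observed/expected normalization
#'
#' Expected contact at distance `d = |i - j|` is the mean balanced value
#' over non-masked pixels on that diagonal; O/E divides the balanced matrix
#' by its expected value. Masked bins and zero-expected diagonals yield NA.
#'
#' @param cm balanced `contact_matrix` (from [ice_balance()]).
#' @return `contact_matrix` with an `oe` matrix and `expected` vector added.
#' @export
observed_expected <- function(cm) {
  if (is.null(cm$balanced)) stop("balance the matrix first (ice_balance)")
  b <- cm$balanced
  n <- nrow(b)
  ok <- !cm$mask
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  okpix <- outer(ok, ok)
  expected <- vapply(0:(n - 1L), function(dd) {
    v <- b[d == dd & okpix]
    if (length(v) == 0L) return(NA_real_)
    mean(v)
  }, numeric(1))
  oe <- b / matrix(expected[d + 1L], n, n)
  oe[!okpix] <- NA
  oe[is.infinite(oe)] <- NA
  cm$expected <- expected
  cm$oe <- oe
  cm
}

#' Aggregate peak analysis (APA) at anchor pairs
#'
#' Per anchor pair, the mean O/E value over the square
#' `(2 flank + 1) x (2 flank + 1)` window centered on the pixel, excluding
#' masked pixels. Windows with more than half their pixels masked are
#' flagged low-confidence.
#'
#' @param cm O/E-normalized `contact_matrix` (from [observed_expected()]).
#' @param anchors data.frame with 1-based bin columns `i`, `j` (and
#'   optionally `label`).
#' @param flank half-width of the window in bins (default 2).
#' @return data.frame: i, j, label, apa, frac_masked, low_confidence;
#'   attribute `stack` holds the element-wise mean window.
#' @export
apa <- function(cm, anchors, flank = 2L) {
  if (is.null(cm$oe)) stop("compute O/E first (observed_expected)")
  n <- nrow(cm$oe)
  k <- 2L * flank + 1L
  stack <- matrix(0, k, k)
  stack_n <- matrix(0, k, k)
  out <- lapply(seq_len(nrow(anchors)), function(a) {
    i <- anchors$i[a]; j <- anchors$j[a]
    if (i - flank < 1L || j - flank < 1L || i + flank > n || j + flank > n) {
      stop(sprintf("anchor (%d, %d) window out of bounds", i, j))
    }
    win <- cm$oe[(i - flank):(i + flank), (j - flank):(j + flank)]
    fm <- mean(is.na(win))
    data.frame(i = i, j = j,
               label = if (!is.null(anchors$label)) anchors$label[a] else
                 sprintf("%d-%d", i, j),
               apa = mean(win, na.rm = TRUE), frac_masked = fm,
               low_confidence = fm > 0.5, stringsAsFactors = FALSE)
  })
  for (a in seq_len(nrow(anchors))) {
    win <- cm$oe[(anchors$i[a] - flank):(anchors$i[a] + flank),
                 (anchors$j[a] - flank):(anchors$j[a] + flank)]
    ok <- !is.na(win)
    stack[ok] <- stack[ok] + win[ok]
    stack_n <- stack_n + ok
  }
  res <- do.call(rbind, out)
  attr(res, "stack") <- stack / pmax(stack_n, 1)
  res
}

#' APA ratio between control and perturbed matrices
#'
#' Per anchor: `APA(control) / APA(perturbed)`. A depleted loop in the
#' perturbed sample yields a ratio above 1 equal to the depletion factor.
#'
#' @param control,perturbed O/E-normalized `contact_matrix` objects on the
#'   same bin grid.
#' @param anchors as in [apa()].
#' @param flank window half-width (default 2).
#' @return data.frame: i, j, label, apa_control, apa_perturbed, ratio.
#' @export
apa_ratio <- function(control, perturbed, anchors, flank = 2L) {
  if (nrow(control$oe) != nrow(perturbed$oe)) stop("bin grids differ")
  a1 <- apa(control, anchors, flank)
  a2 <- apa(perturbed, anchors, flank)
  ratio <- a1$apa / a2$apa
  bad <- !is.finite(ratio) | a2$apa == 0
  if (any(bad)) {
    warning("zero or masked perturbed APA; ratio set NA")
    ratio[bad] <- NA
  }
  data.frame(i = a1$i, j = a1$j, label = a1$label,
             apa_control = a1$apa, apa_perturbed = a2$apa, ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Differential contact map
#'
#' Pixel-wise `log2((A + eps) / (B + eps))` of two balanced (or O/E)
#' matrices on the same grid; masked where either side is masked.
#'
#' @param a,b balanced `contact_matrix` objects.
#' @param pseudocount eps; default half the smallest positive balanced
#'   value across both matrices.
#' @param use `"balanced"` (default) or `"oe"`.
#' @return numeric matrix of log2 ratios (NA where masked).
#' @export
differential_map <- function(a, b, pseudocount = NULL,
                             use = c("balanced", "oe")) {
  use <- match.arg(use)
  ma <- a[[use]]; mb <- b[[use]]
  if (is.null(ma) || is.null(mb)) stop("matrices must be ", use)
  if (!all(dim(ma) == dim(mb))) stop("bin grids differ")
  if (is.null(pseudocount)) {
    v <- c(ma[ma > 0 & !is.na(ma)], mb[mb > 0 & !is.na(mb)])
    pseudocount <- if (length(v)) min(v) / 2 else 1e-6
  }
  out <- log2((ma + pseudocount) / (mb + pseudocount))
  out[is.na(ma) | is.na(mb)] <- NA
  maskpix <- outer(a$mask | b$mask, a$mask | b$mask, "|")
  out[maskpix] <- NA
  out
}

#' Coarsen a contact matrix to a lower resolution
#'
#' Sums raw counts in `factor x factor` blocks (a trailing partial block is
#' kept); balancing must be recomputed at the new resolution.
#'
#' @param cm `contact_matrix`.
#' @param factor integer coarsening factor.
#' @return raw-count `contact_matrix` at `resolution * factor`.
#' @export
coarsen <- function(cm, factor) {
  factor <- as.integer(factor)
  n <- nrow(cm$counts)
  grp <- ceiling(seq_len(n) / factor)
  agg <- rowsum(t(rowsum(cm$counts, grp)), grp)
  contact_matrix(agg, resolution = cm$resolution * factor,
                 chrom = cm$chrom, offset = cm$offset)
}
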