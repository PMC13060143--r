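# Negative-binomial log-linear testing machinery shared by the window-level
# STARR activity test and the guide-level screen test. Deliberately simpler
# than edgeR/DESeq2: method-of-moments dispersions shrunk toward an
# abundance trend, then per-feature GLM fits with a Wald t test whose
# degrees of freedom are inflated by the shrinkage prior.

# Per-feature method-of-moments NB dispersion given a group structure.
# counts: features x samples; groups: factor per sample; offsets: log
# effective library size per sample. Returns raw (possibly negative) MoM
# estimates plus the residual df.
.nb_mom_dispersion <- function(counts, groups, offsets) {
  groups <- as.factor(groups)
  sc <- exp(offsets - mean(offsets))        # relative effective depth
  norm <- sweep(counts, 2L, sc, "/")        # depth-adjusted counts
  df_resid <- ncol(counts) - nlevels(groups)
  if (df_resid <= 0) stop("no residual degrees of freedom for dispersion")
  disp <- numeric(nrow(counts))
  for (g in levels(groups)) {
    j <- which(groups == g)
    gm <- rowMeans(norm[, j, drop = FALSE])
    mu <- outer(gm, sc[j])                  # fitted means on the raw scale
    y <- counts[, j, drop = FALSE]
    disp <- disp + rowSums(((y - mu)^2 - mu) / pmax(mu, 1e-8)^2)
  }
  list(raw = disp / df_resid, df_resid = df_resid)
}

# Trend-shrunk dispersions: lowess fit of MoM dispersion against log2 mean
# abundance, then feature-wise shrinkage toward the trend with prior_df
# pseudo-degrees of freedom.
.nb_shrunk_dispersion <- function(counts, groups, offsets, prior_df = 10,
                                  floor = 1e-6) {
  mom <- .nb_mom_dispersion(counts, groups, offsets)
  ab <- log2(rowMeans(sweep(counts, 2L, exp(offsets), "/")) * 1e6 + 0.5)
  ok <- is.finite(mom$raw) & is.finite(ab)
  trend <- rep(stats::median(pmax(mom$raw[ok], floor)), nrow(counts))
  if (sum(ok) >= 20) {
    lw <- stats::lowess(ab[ok], mom$raw[ok], f = 0.5)
    trend <- stats::approx(lw$x, lw$y, xout = ab, rule = 2,
                           ties = mean)$y
  }
  trend <- pmax(trend, floor)
  raw <- pmax(mom$raw, floor)
  shrunk <- (prior_df * trend + mom$df_resid * raw) / (prior_df + mom$df_resid)
  list(dispersion = pmax(shrunk, floor), trend = trend, raw = mom$raw,
       df_resid = mom$df_resid, prior_df = prior_df)
}

# Vectorized two-group NB Wald test across features. For each feature the
# model is log mu = b_g + offset with one b per group; the tested effect is
# b_group - b_input. Group log-means are fit by Fisher scoring (vectorized
# over features); the Wald SE comes from the per-group Fisher information.
# Group totals of zero are floored at 1/8 pseudo-fragment to keep the
# estimate finite (conservative: the information stays small).
# counts: features x samples (contrast samples only); grp: logical per
# sample (TRUE = treatment); dispersion: per-feature.
.nb_two_group_test <- function(counts, grp, offsets, dispersion, df) {
  fit_group <- function(j) {
    y <- counts[, j, drop = FALSE]
    off <- offsets[j]
    tot <- pmax(rowSums(y), 0.125)
    b <- log(tot / sum(exp(off)))
    for (it in 1:25) {
      mu <- exp(b + rep(off, each = nrow(y)))
      dim(mu) <- dim(y)
      denom <- 1 + dispersion * mu
      score <- rowSums((y - mu) / denom)
      info <- rowSums(mu / denom)
      step <- score / pmax(info, 1e-12)
      step <- pmax(pmin(step, 2), -2)   # damped
      b <- b + step
      if (max(abs(step)) < 1e-10) break
    }
    mu <- exp(b + rep(off, each = nrow(y)))
    dim(mu) <- dim(y)
    info <- rowSums(mu / (1 + dispersion * mu))
    list(b = b, info = info)
  }
  f0 <- fit_group(which(!grp))
  f1 <- fit_group(which(grp))
  est <- f1$b - f0$b
  se <- sqrt(1 / f0$info + 1 / f1$info)
  tstat <- est / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  data.frame(est = est, se = se, p = p)
}

# One NB GLM fit via glm.fit with fixed dispersion; returns the coefficient,
# its standard error, and a two-sided Wald t p-value at the supplied df.
# X must contain an intercept column; `coef` indexes the tested column.
.nb_wald_fit <- function(y, X, offsets, dispersion, coef = 2L, df = Inf) {
  theta <- min(1 / max(dispersion, 1e-8), 1e8)
  fam <- MASS::negative.binomial(theta = theta)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, offset = offsets, family = fam,
                   control = list(maxit = 50))
  )
  beta <- fit$coefficients[coef]
  w <- fit$weights
  XtWX <- crossprod(X * w, X)
  V <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(V) || !is.finite(beta)) {
    return(c(est = NA_real_, se = NA_real_, p = NA_real_))
  }
  se <- sqrt(V[coef, coef])
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  c(est = beta, se = se, p = p)
}
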