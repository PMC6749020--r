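# Negative-binomial Wald differential abundance.
#
# A deliberately compact NB GLM pipeline for two-group designs on raw
# integer counts: median-of-ratios size factors, per-taxon Cox-Reid
# adjusted profile-likelihood dispersion moderated toward a mean-dispersion
# trend, a vectorized IRLS fit of intercept + group with log size-factor
# offsets, and a Wald z test on the group log2 fold change with BH
# correction. No empirical-Bayes fold-change shrinkage and no outlier
# refitting: the goal is the enriched-taxon *set*, validated by the
# recovery and calibration simulations in the test suite.

get_counts <- function(x) {
  m <- if (inherits(x, "community_table")) x$counts else as.matrix(x)
  if (any(abs(m - round(m)) > 1e-8)) stopf("raw integer counts required")
  m
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's counts are divided by
#' the per-taxon geometric mean across samples, and the median of those
#' ratios over reference taxa (taxa with nonzero counts in every sample)
#' is the sample's factor. When no taxon is nonzero everywhere, the
#' geometric means and medians are computed over positive counts only
#' (logged fallback). Factors are normalized to geometric mean 1.
#'
#' @param x a [community_table()] of raw counts, or a samples x taxa matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  counts <- get_counts(x)
  all_pos <- colSums(counts > 0) == nrow(counts)
  if (any(all_pos)) {
    ref <- counts[, all_pos, drop = FALSE]
    log_geo <- colMeans(log(ref))
    s <- apply(ref, 1L, function(r) exp(median(log(r) - log_geo)))
  } else {
    warnf("no taxon present in every sample; using positive-count median-of-ratios")
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    log_geo <- colMeans(logc, na.rm = TRUE)
    s <- apply(counts, 1L, function(r) {
      ratios <- log(r) - log_geo
      exp(median(ratios[is.finite(ratios)]))
    })
  }
  s <- s / exp(mean(log(s)))
  setNames(s, rownames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control across taxa (`p.adjust`).
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

# NB log-likelihood per taxon at dispersion alpha (scalar), plus the
# Cox-Reid adjustment for the intercept+group design; vectorized over taxa.
nb_cr_loglik <- function(Y, mu, alpha, g2) {
  # alpha is per taxon (columns); expand explicitly so arithmetic never
  # relies on column-major recycling
  A <- matrix(alpha, nrow(Y), ncol(Y), byrow = TRUE)
  inv <- 1 / A
  am <- A * mu
  ll <- lgamma(Y + inv) - lgamma(inv) +
    Y * log(am / (1 + am)) - inv * log1p(am)
  ll[Y == 0 & mu == 0] <- 0
  w <- mu / (1 + am)
  cr <- 0.5 * (log(pmax(colSums(w[!g2, , drop = FALSE]), 1e-300)) +
               log(pmax(colSums(w[g2, , drop = FALSE]), 1e-300)))
  colSums(ll) - cr
}

# per-taxon dispersion by zoomed grid search over log alpha; with
# `log_prior_mean`/`prior_var` set, maximizes the penalized (MAP)
# objective instead of the plain Cox-Reid likelihood
estimate_dispersion_grid <- function(Y, mu, g2, lower = 1e-8, upper = 100,
                                     log_prior_mean = NULL, prior_var = NULL) {
  m <- ncol(Y)
  lo <- rep(log(lower), m); hi <- rep(log(upper), m)
  best <- (lo + hi) / 2
  for (round in 1:3) {
    n_grid <- if (round == 1) 36L else 12L
    ll <- matrix(-Inf, m, n_grid)
    grids <- vapply(seq_len(n_grid),
                    function(i) lo + (hi - lo) * (i - 1) / (n_grid - 1),
                    numeric(m))
    if (m == 1L) grids <- matrix(grids, nrow = 1L)
    for (i in seq_len(n_grid)) {
      obj <- nb_cr_loglik(Y, mu, exp(grids[, i]), g2)
      if (!is.null(log_prior_mean))
        obj <- obj - (grids[, i] - log_prior_mean)^2 / (2 * prior_var)
      ll[, i] <- obj
    }
    pick <- max.col(ll, ties.method = "first")
    best <- grids[cbind(seq_len(m), pick)]
    step <- (hi - lo) / (n_grid - 1)
    lo <- pmax(best - step, log(lower)); hi <- pmin(best + step, log(upper))
  }
  exp(best)
}

# mean-dispersion trend: lowess of log dispersion on log mean (robust to
# the heavy spread of per-taxon estimates); falls back to the median for
# tiny taxon sets
fit_dispersion_trend <- function(base_mean, disp, floor) {
  use <- is.finite(disp) & disp > floor * 2 & base_mean > 0
  if (sum(use) < 10)
    return(pmax(rep(median(disp, na.rm = TRUE), length(disp)), floor))
  lx <- log(base_mean[use]); ly <- log(disp[use])
  fit <- stats::lowess(lx, ly, f = 0.5, iter = 3)
  pred <- stats::approx(fit$x, fit$y, xout = log(pmax(base_mean, 1e-8)),
                        rule = 2, ties = "ordered")$y
  trend <- pmax(exp(pred), floor)
  # the lowess centers the log ratios; recalibrate to the (outlier-trimmed)
  # mean ratio so the trend matches dispersion level, not just its median
  ratio <- disp[use] / trend[use]
  ratio <- ratio[ratio > 1 / 8 & ratio < 8]
  if (length(ratio) >= 10) trend <- trend * mean(ratio)
  pmax(trend, floor)
}

# vectorized IRLS for the intercept + group NB GLM with log(sf) offsets
nb_irls <- function(Y, sf, g2, alpha, max_iter = 50, tol = 1e-8) {
  n <- nrow(Y); m <- ncol(Y)
  A <- matrix(alpha, n, m, byrow = TRUE)
  S <- matrix(sf, n, m)
  sum1 <- colSums(Y[!g2, , drop = FALSE]); d1 <- sum(sf[!g2])
  sum2 <- colSums(Y[g2, , drop = FALSE]); d2 <- sum(sf[g2])
  q1 <- (sum1 + 0.5) / d1; q2 <- (sum2 + 0.5) / d2
  b0 <- log(q1); b2 <- log(q2) - log(q1)
  G2 <- matrix(g2, n, m)
  for (it in seq_len(max_iter)) {
    eta <- matrix(b0, n, m, byrow = TRUE) + G2 * matrix(b2, n, m, byrow = TRUE)
    mu <- S * exp(eta)
    mu <- pmax(mu, 1e-10)
    W <- mu / (1 + A * mu)
    Z <- eta + (Y - mu) / mu
    WZ <- W * Z
    Sw <- colSums(W); Sw2 <- colSums(W * G2)
    Swz <- colSums(WZ); Swz2 <- colSums(WZ * G2)
    det <- pmax(Sw * Sw2 - Sw2^2, 1e-300)
    new_b2 <- (Sw * Swz2 - Sw2 * Swz) / det
    new_b0 <- (Swz - Sw2 * new_b2) / Sw
    new_b2 <- pmin(pmax(new_b2, -15), 15)
    new_b0 <- pmin(pmax(new_b0, -50), 50)
    delta <- max(abs(new_b0 - b0), abs(new_b2 - b2))
    b0 <- new_b0; b2 <- new_b2
    if (delta < tol) break
  }
  eta <- matrix(b0, n, m, byrow = TRUE) + G2 * matrix(b2, n, m, byrow = TRUE)
  mu <- pmax(S * exp(eta), 1e-10)
  W <- mu / (1 + A * mu)
  Sw <- colSums(W); Sw2 <- colSums(W * G2)
  se_b2 <- sqrt(Sw / pmax(Sw * Sw2 - Sw2^2, 1e-300))
  list(b0 = b0, b2 = b2, se_b2 = se_b2, mu = mu)
}

#' Negative-binomial Wald differential-abundance test
#'
#' Fits, per taxon, a negative-binomial GLM with log link, log size-factor
#' offsets and design `~ group` (two levels; the first level is the
#' reference, so positive fold changes mean enrichment in the second
#' level). Dispersion is estimated per taxon by Cox-Reid adjusted profile
#' maximum likelihood, then moderated toward a fitted mean-dispersion
#' trend; significance is a two-sided Wald test on the group coefficient
#' (t reference with n - 2 degrees of freedom) with Benjamini-Hochberg
#' correction across taxa.
#'
#' @param x a [community_table()] of raw integer counts, or a samples x
#'   taxa matrix.
#' @param groups two-level factor-like vector, one entry per sample, each
#'   level with at least 2 samples. The first level (of `factor(groups)`)
#'   is the reference.
#' @param alpha_floor lower bound on the dispersion (default 1e-8).
#' @param prior_sdlog log-scale standard deviation of the dispersion prior
#'   around the trend; `NULL` (default) sets it adaptively from the spread
#'   of the per-taxon estimates around the trend in excess of their
#'   sampling variance.
#' @param min_sample_depth optional: drop samples whose total count is
#'   below this before testing (low-abundance sample exclusion).
#' @param min_base_mean optional independent filter: taxa with mean
#'   normalized count below this are excluded before BH (default `NULL`,
#'   off).
#' @return an object of class `diffabund`: element `results` is a
#'   data.frame (taxon, baseMean, log2FoldChange, lfcSE, stat, pvalue,
#'   padj), plus `size_factors`, `dispersion` (per-taxon final, ML and
#'   trend), `excluded_taxa` (all-zero), and the group levels.
#' @export
nb_wald <- function(x, groups, alpha_floor = 1e-8, prior_sdlog = NULL,
                    min_sample_depth = NULL, min_base_mean = NULL) {
  counts <- get_counts(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stopf("exactly 2 groups required")
  if (length(groups) != nrow(counts)) stopf("one group label per sample required")
  if (any(table(groups) < 2L)) stopf("every group needs at least 2 samples")
  if (!is.null(min_sample_depth)) {
    keep <- rowSums(counts) >= min_sample_depth
    if (any(!keep)) {
      warnf("excluding %d low-abundance sample(s) below depth %s",
            sum(!keep), format(min_sample_depth))
      counts <- counts[keep, , drop = FALSE]
      groups <- droplevels(groups[keep])
      if (nlevels(groups) != 2L || any(table(groups) < 2L))
        stopf("low-abundance exclusion left fewer than 2 samples in a group")
    }
  }
  nonzero <- colSums(counts) > 0
  excluded <- colnames(counts)[!nonzero]
  Y <- counts[, nonzero, drop = FALSE]
  sf <- size_factors(counts)
  g2 <- groups == levels(groups)[2L]
  n <- nrow(Y)

  # group-mean fitted values for dispersion estimation
  q1 <- colSums(Y[!g2, , drop = FALSE]) / sum(sf[!g2])
  q2 <- colSums(Y[g2, , drop = FALSE]) / sum(sf[g2])
  q <- rbind(q1, q2)[(g2 + 1L), , drop = FALSE]
  mu0 <- q * matrix(sf, n, ncol(Y))

  disp_ml <- estimate_dispersion_grid(Y, mu0, g2, lower = alpha_floor)
  base_mean <- colMeans(Y / sf)
  disp_trend <- fit_dispersion_trend(base_mean, disp_ml, alpha_floor)
  if (is.null(prior_sdlog)) {
    # adaptive prior width: biological spread of log dispersion around the
    # trend (taken robustly) in excess of the estimates' sampling variance
    resid <- log(pmax(disp_ml, alpha_floor)) - log(disp_trend)
    s2_samp <- trigamma((n - 2) / 2)
    prior_var <- max(stats::mad(resid, na.rm = TRUE)^2 - s2_samp, 0.25^2)
  } else prior_var <- prior_sdlog^2
  # maximum a posteriori dispersion: penalized Cox-Reid likelihood with a
  # log-normal prior centered on the trend
  disp <- estimate_dispersion_grid(Y, mu0, g2, lower = alpha_floor,
                                   log_prior_mean = log(disp_trend),
                                   prior_var = prior_var)
  disp <- pmax(disp, alpha_floor)

  fit <- nb_irls(Y, sf, g2, disp)
  log2fc <- fit$b2 / log(2)
  lfc_se <- fit$se_b2 / log(2)
  z <- fit$b2 / fit$se_b2
  # t reference with n - 2 df: the usual small-sample correction for a
  # Wald statistic with estimated dispersion
  pvalue <- 2 * pt(-abs(z), df = n - 2L)
  padj <- rep(NA_real_, length(pvalue))
  test_set <- if (is.null(min_base_mean)) rep(TRUE, length(pvalue))
              else base_mean >= min_base_mean
  padj[test_set] <- bh_adjust(pvalue[test_set])
  res <- data.frame(taxon = colnames(Y), baseMean = base_mean,
                    log2FoldChange = log2fc, lfcSE = lfc_se, stat = z,
                    pvalue = pvalue, padj = padj, row.names = NULL)
  structure(list(results = res, size_factors = sf,
                 dispersion = data.frame(taxon = colnames(Y),
                                         final = disp, ml = disp_ml,
                                         trend = disp_trend),
                 excluded_taxa = excluded,
                 reference = levels(groups)[1L],
                 contrast = levels(groups)[2L]),
            class = "diffabund")
}

#' @export
print.diffabund <- function(x, ...) {
  n_sig <- sum(x$results$padj < 0.05, na.rm = TRUE)
  cat(sprintf("NB Wald differential abundance: %s vs %s (reference)\n",
              x$contrast, x$reference))
  cat(sprintf("  %d taxa tested, %d at padj < 0.05 (%d enriched)\n",
              nrow(x$results), n_sig,
              sum(x$results$padj < 0.05 & x$results$log2FoldChange > 0,
                  na.rm = TRUE)))
  invisible(x)
}

#' Write a differential-abundance results table as TSV
#'
#' @param da a [nb_wald()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_diffabund <- function(da, path) {
  write.table(da$results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
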