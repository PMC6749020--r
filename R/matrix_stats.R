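# Permutation inference on distance matrices: Mantel, partial Mantel,
# distance-decay regression, slope-difference randomization, PERMANOVA.
#
# All tests report p = (#{permuted statistic at least as extreme} + 1) /
# (n_permutations + 1) and are exactly reproducible given a seed.

perm_result <- function(statistic, n_perm, p_value, tail, seed, ...) {
  structure(c(list(statistic = statistic, n_perm = n_perm, p_value = p_value,
                   tail = tail, seed = seed), list(...)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: statistic = %.4g, p = %.4g (%d permutations, tail=%s)\n",
              x$statistic, x$p_value, x$n_perm, x$tail))
  invisible(x)
}

check_aligned <- function(...) {
  mats <- list(...)
  ids <- rownames(mats[[1L]])
  for (m in mats[-1L])
    if (!identical(rownames(m), ids))
      stopf("distance matrices must share identical sample labels and order")
  if (length(ids) < 4L) stopf("need at least 4 samples")
  invisible(ids)
}

# both matrices are correlated on the dissimilarity scale, so a positive
# Mantel r always means "more different together"
to_dissim_matrix <- function(x) {
  if (inherits(x, "dist_matrix") && attr(x, "transform") == "similarity")
    x <- as_dissimilarity(x)
  unclass_dist(x)
}

perm_pvalue <- function(obs, perm, tail) {
  switch(tail,
    greater = (sum(perm >= obs) + 1) / (length(perm) + 1),
    less = (sum(perm <= obs) + 1) / (length(perm) + 1),
    two.sided = (sum(abs(perm) >= abs(obs)) + 1) / (length(perm) + 1),
    auto = if (obs >= 0) (sum(perm >= obs) + 1) / (length(perm) + 1)
           else (sum(perm <= obs) + 1) / (length(perm) + 1))
}

#' Mantel test between two distance matrices
#'
#' Pearson (or Spearman) correlation over the n(n-1)/2 off-diagonal pairs;
#' the null distribution is built by simultaneously permuting rows and
#' columns of the first matrix. Similarity-tagged matrices are converted to
#' dissimilarities internally, so the statistic always correlates two
#' dissimilarities. The default tail is one-sided in the direction of the
#' observed statistic.
#'
#' @param A,B [dist_matrix()] objects over the same samples in the same order.
#' @param n_perm number of permutations (default 999).
#' @param tail `"auto"` (one-sided, direction of the observed r),
#'   `"greater"`, `"less"`, or `"two.sided"`.
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @param seed optional integer seed.
#' @return a `perm_test` with elements `statistic` (Mantel r), `p_value`,
#'   `n_perm`, `tail`, `seed`.
#' @export
mantel_test <- function(A, B, n_perm = 999, tail = c("auto", "greater", "less", "two.sided"),
                        method = c("pearson", "spearman"), seed = NULL) {
  tail <- match.arg(tail); method <- match.arg(method)
  check_aligned(A, B)
  a <- to_dissim_matrix(A); b <- to_dissim_matrix(B)
  lt <- lower.tri(a)
  av <- a[lt]; bv <- b[lt]
  if (sd(av) == 0 || sd(bv) == 0)
    stopf("zero variance in off-diagonal distances")
  if (method == "spearman") { av <- rank(av); bv <- rank(bv) }
  obs <- cor(av, bv)
  n <- nrow(a)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    ap <- a[p, p][lt]
    if (method == "spearman") ap <- rank(ap)
    cor(ap, bv)
  }, numeric(1L)))
  perm_result(obs, n_perm, perm_pvalue(obs, perm, tail), tail, seed,
              method = method)
}

partial_r <- function(rab, rac, rbc) {
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

#' Partial Mantel test
#'
#' Correlation between two distance matrices after removing, from each, its
#' linear dependence on a third (the residual correlation of `A ~ C` with
#' `B ~ C` over off-diagonal pairs). The null permutes rows/columns of the
#' raw first matrix.
#'
#' @inheritParams mantel_test
#' @param C the conditioning [dist_matrix()] (e.g. geographic distance).
#' @return a `perm_test`; `statistic` is the partial Mantel r.
#' @export
partial_mantel <- function(A, B, C, n_perm = 999,
                           tail = c("auto", "greater", "less", "two.sided"),
                           method = c("pearson", "spearman"), seed = NULL) {
  tail <- match.arg(tail); method <- match.arg(method)
  check_aligned(A, B, C)
  a <- to_dissim_matrix(A); b <- to_dissim_matrix(B); c_ <- to_dissim_matrix(C)
  lt <- lower.tri(a)
  av <- a[lt]; bv <- b[lt]; cv <- c_[lt]
  if (method == "spearman") { av <- rank(av); bv <- rank(bv); cv <- rank(cv) }
  rbc <- cor(bv, cv)
  obs <- partial_r(cor(av, bv), cor(av, cv), rbc)
  n <- nrow(a)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    ap <- a[p, p][lt]
    if (method == "spearman") ap <- rank(ap)
    partial_r(cor(ap, bv), cor(ap, cv), rbc)
  }, numeric(1L)))
  perm_result(obs, n_perm, perm_pvalue(obs, perm, tail), tail, seed,
              method = method)
}

#' Distance-decay regression
#'
#' Ordinary least squares of pairwise community (or environmental)
#' similarity on pairwise geographic distance over the off-diagonal pairs,
#' with the significance of the association assessed by a Mantel test
#' between the corresponding dissimilarity and distance matrices. Distance
#' is log10-transformed by default, so the slope is "similarity lost per
#' decade of distance"; set `log10_distance = FALSE` for a linear axis.
#'
#' @param similarity a similarity-tagged [dist_matrix()] (use
#'   [as_similarity()] on a Canberra or Gower matrix).
#' @param geo a geographic [dist_matrix()] with positive off-diagonal
#'   entries when `log10_distance` is `TRUE`.
#' @param log10_distance regress on log10 distance (default `TRUE`).
#' @param n_perm,seed passed to [mantel_test()].
#' @return an object of class `decay_fit`: `slope`, `intercept`,
#'   `mantel_r`, `mantel_p`, `significant` (Mantel p < 0.05; by the usual
#'   plotting convention a trend line is drawn only then), `n_pairs`, and
#'   `pairs` (data.frame of distance and similarity, on the fitted scale).
#' @export
decay_fit <- function(similarity, geo, log10_distance = TRUE,
                      n_perm = 999, seed = NULL) {
  if (!inherits(similarity, "dist_matrix") ||
      attr(similarity, "transform") != "similarity")
    stopf("'similarity' must be a similarity-tagged dist_matrix")
  check_aligned(similarity, geo)
  lt <- lower.tri(similarity)
  s <- unclass_dist(similarity)[lt]
  d <- unclass_dist(geo)[lt]
  if (log10_distance) {
    if (any(d <= 0)) stopf("non-positive distances: log10 transform undefined")
    d <- log10(d)
  }
  fit <- lm.fit(cbind(1, d), s)
  mt <- mantel_test(similarity, geo, n_perm = n_perm, seed = seed)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 transform = if (log10_distance) "log10" else "linear",
                 mantel_r = mt$statistic, mantel_p = mt$p_value,
                 significant = mt$p_value < 0.05,
                 n_pairs = length(s),
                 pairs = data.frame(distance = d, similarity = s)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("distance-decay: slope = %.4g per %s distance, Mantel r = %.3f, p = %.4g%s\n",
              x$slope, if (x$transform == "log10") "decade of" else "unit",
              x$mantel_r, x$mantel_p,
              if (x$significant) "" else " (not significant; no trend line)"))
  invisible(x)
}

ols_slope <- function(x, y) cov(x, y) / var(x)

#' Randomization test for a difference between two decay slopes
#'
#' The observed statistic is `slope1 - slope2` of the two
#' (distance, similarity) pair sets. Under the null the pairs carry no
#' dataset identity, so pair-set membership is reshuffled between the two
#' sets (preserving their sizes) and both slopes are refit at each
#' permutation; the p-value is the fraction of permutations whose slope
#' difference is at least as extreme as the observed one (+1 correction).
#' Two-sided on the absolute difference by default; a one-sided variant is
#' available.
#'
#' @param pairs1,pairs2 data.frames with columns `distance` and
#'   `similarity` (e.g. the `pairs` element of a [decay_fit()]), each with
#'   at least 3 rows.
#' @param n_perm number of membership reshuffles (default 1000).
#' @param tail `"two.sided"` (default) or `"one.sided"` (direction of the
#'   observed difference).
#' @param seed optional integer seed.
#' @return a `perm_test`; `statistic` is the observed slope difference,
#'   with elements `slope1` and `slope2` attached.
#' @export
diffslope <- function(pairs1, pairs2, n_perm = 1000,
                      tail = c("two.sided", "one.sided"), seed = NULL) {
  tail <- match.arg(tail)
  for (p in list(pairs1, pairs2))
    if (!all(c("distance", "similarity") %in% names(p)) || nrow(p) < 3L)
      stopf("each pair set needs columns distance/similarity and >= 3 rows")
  s1 <- ols_slope(pairs1$distance, pairs1$similarity)
  s2 <- ols_slope(pairs2$distance, pairs2$similarity)
  obs <- s1 - s2
  x <- c(pairs1$distance, pairs2$distance)
  y <- c(pairs1$similarity, pairs2$similarity)
  n1 <- nrow(pairs1); n <- length(x)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n, n1)
    ols_slope(x[idx], y[idx]) - ols_slope(x[-idx], y[-idx])
  }, numeric(1L)))
  pv <- if (tail == "two.sided") perm_pvalue(obs, perm, "two.sided")
        else perm_pvalue(obs, perm, "auto")
  perm_result(obs, n_perm, pv, tail, seed, slope1 = s1, slope2 = s2)
}

permanova_stats <- function(d2, groups, lt) {
  n <- nrow(d2)
  g <- length(unique(groups))
  ss_total <- sum(d2[lt]) / n
  ss_within <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    ss_within <- ss_within + sum(d2[idx, idx][lower.tri(d2[idx, idx])]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  f <- (ss_among / (g - 1)) / (ss_within / (n - g))
  c(f = f, r2 = ss_among / ss_total)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total
#' sum of squared distances into among- and within-group components,
#' forming a pseudo-F; significance comes from permuting the group labels.
#'
#' @param D a [dist_matrix()] (dissimilarity scale).
#' @param groups factor-like group membership, one entry per sample, with
#'   at least 2 groups of at least 2 samples each.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed.
#' @return a `perm_test`; `statistic` is the pseudo-F, with `r2` (the
#'   among-group fraction of the total sum of squares) and degrees of
#'   freedom attached.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL) {
  d <- to_dissim_matrix(D)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stopf("one group label per sample required")
  tabg <- table(groups)
  if (length(tabg) < 2L) stopf("need at least 2 groups")
  if (any(tabg < 2L)) stopf("every group needs at least 2 samples")
  d2 <- d^2
  lt <- lower.tri(d2)
  obs <- permanova_stats(d2, groups, lt)
  n <- nrow(d2)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    permanova_stats(d2, groups[sample.int(n)], lt)[["f"]]
  }, numeric(1L)))
  res <- perm_result(unname(obs[["f"]]), n_perm,
                     perm_pvalue(obs[["f"]], perm, "greater"),
                     "greater", seed)
  res$r2 <- unname(obs[["r2"]])
  res$df <- c(length(tabg) - 1L, n - length(tabg))
  res
}
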