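# Within-group similarity summaries and classical group comparisons.
#
# Pairwise similarities within a group are not independent observations
# (each sample enters n-1 pairs), so the classical ANOVA/Tukey/t results
# on pair vectors are reported together with their pair counts, and a
# sample-level permutation alternative is provided as a robustness check.

#' Mean within-group pairwise similarity
#'
#' Mean and standard error, over the within-group off-diagonal pairs, of
#' `1 - d`. The pair vector is returned for downstream group comparisons.
#'
#' @param D a [dist_matrix()] on either scale (converted to similarity
#'   internally; community and environment kinds only).
#' @param samples optional subset of sample ids (or logical/integer index)
#'   defining the group; default all samples.
#' @return list with `mean`, `sem`, `n_pairs`, and `pairs` (numeric vector
#'   of pairwise similarities).
#' @export
mean_pairwise_similarity <- function(D, samples = NULL) {
  s <- as_similarity(D)
  m <- unclass_dist(s)
  if (!is.null(samples)) m <- m[samples, samples, drop = FALSE]
  if (nrow(m) < 2L) stopf("group needs at least 2 samples")
  pairs <- m[lower.tri(m)]
  list(mean = mean(pairs), sem = sem(pairs), n_pairs = length(pairs),
       pairs = pairs)
}

#' Within-group similarity pair vectors by group
#'
#' @param D a [dist_matrix()].
#' @param groups group label per sample.
#' @return named list of pairwise-similarity vectors, one per group.
#' @export
similarity_pairs_by_group <- function(D, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(D)) stopf("one group label per sample required")
  lapply(split(seq_along(groups), groups), function(idx)
    mean_pairwise_similarity(D, samples = idx)$pairs)
}

stack_groups <- function(values_by_group) {
  if (length(values_by_group) < 2L) stopf("need at least 2 groups")
  lens <- lengths(values_by_group)
  if (any(lens < 2L)) stopf("every group needs at least 2 values")
  data.frame(value = unlist(values_by_group, use.names = FALSE),
             group = factor(rep(names(values_by_group), lens)))
}

#' One-way ANOVA across groups of values
#'
#' Classical between/within decomposition on pooled values (e.g. pairwise
#' similarities by land type).
#'
#' @param values_by_group named list of numeric vectors.
#' @return list with `F`, `df` (length 2), `p_value`, and the group means.
#' @export
anova_oneway <- function(values_by_group) {
  df <- stack_groups(values_by_group)
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  list(F = tab$`F value`[1L], df = c(tab$Df[1L], tab$Df[2L]),
       p_value = tab$`Pr(>F)`[1L],
       means = vapply(values_by_group, mean, numeric(1L)))
}

#' Tukey honest significant differences across groups
#'
#' Studentized-range adjusted pairwise comparisons after a one-way fit.
#'
#' @inheritParams anova_oneway
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with one row per group pair: `contrast`, `diff`,
#'   `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values_by_group, conf_level = 0.95) {
  df <- stack_groups(values_by_group)
  tk <- TukeyHSD(aov(value ~ group, data = df), conf.level = conf_level)$group
  data.frame(contrast = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL)
}

#' Two-tailed Student's t-test (pooled variance)
#'
#' @param v1,v2 numeric vectors of length >= 2.
#' @return list with `t`, `df`, `p_value`.
#' @export
t_test_two_tailed <- function(v1, v2) {
  if (length(v1) < 2L || length(v2) < 2L) stopf("each vector needs >= 2 values")
  if (sd(v1) == 0 && sd(v2) == 0) {
    if (mean(v1) == mean(v2))
      return(list(t = 0, df = length(v1) + length(v2) - 2L, p_value = 1))
    stopf("zero pooled variance with unequal means: t undefined")
  }
  ht <- t.test(v1, v2, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Permutation test of a between-group mean-similarity gap
#'
#' Robustness companion to the classical tests: because within-group
#' pairwise similarities are pseudoreplicated, this permutes *samples*
#' between the two groups and recomputes the difference in mean within-group
#' similarity each time.
#'
#' @param D a [dist_matrix()] over the union of both groups.
#' @param groups two-level group label per sample.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return a `perm_test`; `statistic` is mean(similarity group 1) -
#'   mean(similarity group 2), two-sided p.
#' @export
similarity_gap_permtest <- function(D, groups, n_perm = 999, seed = NULL) {
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) != 2L) stopf("exactly 2 groups required")
  s <- unclass_dist(as_similarity(D))
  gap <- function(g) {
    i1 <- g == levs[1L]; i2 <- !i1
    mean(s[i1, i1][lower.tri(s[i1, i1])]) - mean(s[i2, i2][lower.tri(s[i2, i2])])
  }
  obs <- gap(groups)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(k)
    gap(sample(groups)), numeric(1L)))
  perm_result(obs, n_perm, perm_pvalue(obs, perm, "two.sided"),
              "two.sided", seed)
}
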