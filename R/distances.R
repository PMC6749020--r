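#' Labeled pairwise (dis)similarity matrix
#'
#' Thin wrapper around a symmetric numeric matrix with a zero diagonal,
#' tagged with what it measures (`kind`: community, environment, or
#' geographic) and what scale it is on (`transform`: `"none"` for a
#' dissimilarity/distance, `"similarity"` for 1 - dissimilarity,
#' `"log10"` for log10 distance).
#'
#' @param m symmetric numeric matrix with sample row/column names.
#' @param kind one of `"community"`, `"environment"`, `"geographic"`.
#' @param transform one of `"none"`, `"similarity"`, `"log10"`.
#' @return an object of class `dist_matrix`.
#' @export
dist_matrix <- function(m, kind = c("community", "environment", "geographic"),
                        transform = c("none", "similarity", "log10")) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("distance matrix must be square")
  if (is.null(rownames(m))) stopf("distance matrix needs sample labels")
  if (max(abs(m - t(m))) > 1e-8) stopf("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-8) && transform != "similarity")
    stopf("distance matrix must have zero diagonal")
  colnames(m) <- rownames(m)
  structure(m, kind = kind, transform = transform,
            class = c("dist_matrix", "matrix", "array"))
}

unclass_dist <- function(x) {
  attr(x, "kind") <- NULL; attr(x, "transform") <- NULL
  unclass(x)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s, transform=%s): %d samples, range %.4g - %.4g\n",
              attr(x, "kind"), attr(x, "transform"), nrow(x),
              min(x[lower.tri(x)]), max(x[lower.tri(x)])))
  invisible(x)
}

lower_vec <- function(m) m[lower.tri(m)]

#' Convert between dissimilarity and similarity
#'
#' Only valid for kinds bounded in \[0,1\] (community and environment).
#'
#' @param x a [dist_matrix()].
#' @return a [dist_matrix()] on the complementary scale.
#' @export
as_similarity <- function(x) {
  if (attr(x, "transform") == "similarity") return(x)
  if (attr(x, "kind") == "geographic" || attr(x, "transform") == "log10")
    stopf("similarity is only defined for [0,1]-bounded dissimilarities")
  out <- 1 - unclass_dist(x)
  dist_matrix(out, kind = attr(x, "kind"), transform = "similarity")
}

#' @rdname as_similarity
#' @export
as_dissimilarity <- function(x) {
  if (attr(x, "transform") != "similarity") return(x)
  out <- 1 - unclass_dist(x)
  diag(out) <- 0
  dist_matrix(out, kind = attr(x, "kind"), transform = "none")
}

#' Canberra community distance
#'
#' For samples x and y the distance is the mean, over the taxa where
#' `x_k + y_k > 0` (double zeros excluded), of `|x_k - y_k| / (x_k + y_k)`,
#' so values lie in \[0,1\] and `1 - d` is a bounded community similarity.
#' This averaged form is what `vegan::vegdist(method = "canberra")`
#' computes, and it does the computation here. The unaveraged textbook sum
#' (the same quantity times the number of contributing taxa) is available
#' with `average = FALSE`.
#'
#' @param tab a [community_table()] (raw or rarefaction-averaged).
#' @param average divide by the number of non-double-zero taxa (default).
#' @return a community [dist_matrix()].
#' @export
canberra <- function(tab, average = TRUE) {
  counts <- tab$counts
  if (nrow(counts) < 2L) stopf("need at least 2 samples")
  d <- as.matrix(vegan::vegdist(counts, method = "canberra"))
  if (any(!is.finite(d)))
    stopf("a sample pair shares no taxon with positive total (empty samples?)")
  if (!average) {
    pres <- counts > 0
    nz <- outer(rowSums(pres), rowSums(pres), "+") - tcrossprod(pres * 1)
    d <- d * nz
    diag(d) <- 0
  }
  dist_matrix(d, kind = "community", transform = "none")
}

#' Gower environmental similarity
#'
#' Gower dissimilarity is the mean over variables of the range-normalized
#' absolute difference `|x_v - y_v| / range_v` (simple matching for factor
#' variables), computed with `cluster::daisy`. The result is returned as a
#' similarity, `1 - dissimilarity`, in \[0,1\]. Variables with zero range
#' carry no information and are dropped with a warning.
#'
#' @param env an [env_table()] or data.frame (factors allowed).
#' @return an environment [dist_matrix()] tagged as a similarity.
#' @export
gower_similarity <- function(env) {
  df <- if (inherits(env, "env_table")) as.data.frame(env$values) else as.data.frame(env)
  if (nrow(df) < 2L) stopf("need at least 2 samples")
  num <- vapply(df, is.numeric, logical(1L))
  rng <- vapply(df[num], function(v) diff(range(v)), numeric(1L))
  if (any(rng == 0)) {
    bad <- names(rng)[rng == 0]
    warnf("dropping zero-range variable(s): %s", paste(bad, collapse = ", "))
    df <- df[, setdiff(names(df), bad), drop = FALSE]
  }
  if (!ncol(df)) stopf("all variables have zero range")
  d <- as.matrix(cluster::daisy(df, metric = "gower"))
  dist_matrix(1 - d, kind = "environment", transform = "similarity")
}

#' Pairwise geographic distance
#'
#' Euclidean distance in meters between sample coordinates.
#'
#' @param x a [community_table()] or a data.frame/matrix with `x`, `y`
#'   columns and sample row names.
#' @param log10_transform return log10 distances (zero distances are an
#'   error under the transform).
#' @return a geographic [dist_matrix()].
#' @export
geographic <- function(x, log10_transform = FALSE) {
  md <- if (inherits(x, "community_table")) x$metadata else as.data.frame(x)
  if (!all(c("x", "y") %in% names(md))) stopf("coordinates 'x','y' required")
  d <- as.matrix(dist(md[, c("x", "y")]))
  if (log10_transform) {
    if (any(lower_vec(d) <= 0))
      stopf("zero geographic distance: log10 transform undefined (duplicate coordinates?)")
    out <- log10(d)
    diag(out) <- 0
    return(dist_matrix(out, kind = "geographic", transform = "log10"))
  }
  if (any(lower_vec(d) == 0))
    warnf("duplicate coordinates: zero off-diagonal geographic distances")
  dist_matrix(d, kind = "geographic", transform = "none")
}

#' Prune highly correlated environmental variables
#'
#' Greedy reduction of collinear soil variables so that pairwise similarity
#' is not inflated by redundant measurements: while any pair of variables
#' has Pearson R^2 above `r2_threshold` at `p < p_threshold`, the member of
#' the worst pair with the larger mean absolute correlation to all other
#' variables is removed. Every removal is logged.
#'
#' @param env an [env_table()].
#' @param r2_threshold squared-correlation threshold (default 0.6).
#' @param p_threshold correlation-test p-value threshold (default 0.05).
#' @return an [env_table()] with attribute `"pruning_log"`, a data.frame of
#'   removed variables with the offending pair and its R^2.
#' @export
prune_correlated <- function(env, r2_threshold = 0.6, p_threshold = 0.05) {
  v <- env$values
  if (ncol(v) < 2L) stopf("need at least 2 variables")
  log <- data.frame(removed = character(), partner = character(),
                    r2 = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (ncol(v) < 2L) break
    cm <- cor(v)
    r2 <- cm^2
    diag(r2) <- 0
    worst <- arrayInd(which.max(r2), dim(r2))
    if (r2[worst] <= r2_threshold) break
    i <- worst[1L]; j <- worst[2L]
    pv <- cor.test(v[, i], v[, j])$p.value
    if (pv >= p_threshold) break
    mean_abs <- rowMeans(abs(cm) - diag(ncol(v)) * abs(cm)) # excludes self
    drop <- if (mean_abs[i] >= mean_abs[j]) i else j
    keep_partner <- if (drop == i) j else i
    log <- rbind(log, data.frame(removed = colnames(v)[drop],
                                 partner = colnames(v)[keep_partner],
                                 r2 = r2[worst]))
    v <- v[, -drop, drop = FALSE]
  }
  out <- env_table(v)
  attr(out, "pruning_log") <- log
  out
}
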