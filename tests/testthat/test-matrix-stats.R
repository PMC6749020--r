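test_that("Mantel statistic: identity, affine invariance, vegan cross-check", {
  A <- random_dist(7, seed = 41)
  expect_equal(mantel_test(A, A, n_perm = 99, seed = 1)$statistic, 1)
  bm <- 0.2 + 0.5 * unclass(A)
  diag(bm) <- 0
  B <- dist_matrix(bm, kind = "community")
  expect_equal(mantel_test(A, B, n_perm = 99, seed = 1)$statistic, 1)
  C <- random_dist(7, seed = 42, kind = "environment")
  ours <- mantel_test(A, C, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(unclass(A)), as.dist(unclass(C)),
                       permutations = 99)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Mantel is invariant to a common relabeling and errors on misalignment", {
  A <- random_dist(6, seed = 43)
  B <- random_dist(6, seed = 44)
  r1 <- mantel_test(A, B, n_perm = 49, seed = 5)$statistic
  p <- c(4, 2, 6, 1, 3, 5)
  Ap <- dist_matrix(unclass(A)[p, p], kind = "community")
  Bp <- dist_matrix(unclass(B)[p, p], kind = "community")
  expect_equal(mantel_test(Ap, Bp, n_perm = 49, seed = 5)$statistic, r1)
  Bbad <- random_dist(6, seed = 44)
  rownames(Bbad) <- colnames(Bbad) <- rev(rownames(Bbad))
  expect_error(mantel_test(A, Bbad, n_perm = 9), "labels")
})

test_that("similarity-tagged matrices are converted so Mantel correlates dissimilarities", {
  A <- random_dist(6, seed = 45)
  S <- as_similarity(A)
  B <- random_dist(6, seed = 46)
  expect_equal(mantel_test(S, B, n_perm = 49, seed = 2)$statistic,
               mantel_test(A, B, n_perm = 49, seed = 2)$statistic)
})

test_that("partial Mantel: irrelevant conditioning keeps r, vegan agrees, B=C nulls out", {
  A <- random_dist(8, seed = 47)
  C <- random_dist(8, seed = 48, kind = "geographic")
  pm <- partial_mantel(A, A, C, n_perm = 49, seed = 1)
  expect_gt(pm$statistic, 0.99)
  B <- random_dist(8, seed = 49, kind = "environment")
  ours <- partial_mantel(A, B, C, n_perm = 49, seed = 1)
  ref <- vegan::mantel.partial(as.dist(unclass(A)), as.dist(unclass(B)),
                               as.dist(unclass(C)), permutations = 49)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  # conditioning on (almost) B itself: partial r of an independent A
  # averages ~0, because C soaks up all of B's signal
  with_seed(50, {
    noise <- matrix(runif(64, 0, 0.01), 8)
    nmat <- pmax(unclass(B) * 0.9 + noise + t(noise), 0) * (1 - diag(8))
    rownames(nmat) <- colnames(nmat) <- rownames(B)
    Bnear <- dist_matrix(nmat, kind = "environment")
    rs <- vapply(1:200, function(k) {
      Ak <- random_dist(8, seed = 1000 + k)
      partial_mantel(Ak, B, Bnear, n_perm = 0, seed = 1)$statistic
    }, numeric(1L))
    expect_lt(abs(mean(rs)), 3 * stats::sd(rs) / sqrt(length(rs)))
  })
})

test_that("permutation p matches exact enumeration on a 4-sample fixture", {
  A <- random_dist(4, seed = 51)
  B <- random_dist(4, seed = 52)
  p_exact <- mantel_exact_p(unclass(A), unclass(B), tail = "greater")
  res <- mantel_test(A, B, n_perm = 999, tail = "greater", seed = 7)
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 999)
})

test_that("decay_fit: two-point slope is -1 per decade; trend-line rule follows Mantel p", {
  # two distinct distances (1 m and 10 m), similarity 1 and 0: a clean
  # one-decade drop; n = 4 so the Mantel permutation is defined
  smat <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  gmat <- matrix(1, 4, 4, dimnames = dimnames(smat))
  smat[cbind(c(3, 4, 1, 2), c(1, 2, 3, 4))] <- 0
  gmat[cbind(c(3, 4, 1, 2), c(1, 2, 3, 4))] <- 10
  diag(smat) <- 1; diag(gmat) <- 0
  S <- dist_matrix(smat, kind = "community", transform = "similarity")
  G <- dist_matrix(gmat, kind = "geographic")
  fit <- decay_fit(S, G, n_perm = 99, seed = 3)
  expect_equal(fit$slope, -1, tolerance = 1e-10)
  expect_identical(fit$significant, fit$mantel_p < 0.05)
  expect_error(decay_fit(S, dist_matrix(0 * gmat, kind = "geographic"),
                         n_perm = 9), "log10")
})

test_that("decay slope is near zero when similarity is independent of distance", {
  with_seed(61, {
    slopes <- vapply(1:100, function(k) {
      n <- 10
      s <- matrix(0, n, n); s[lower.tri(s)] <- runif(n * (n - 1) / 2, 0.2, 0.4)
      s <- s + t(s); diag(s) <- 1
      rownames(s) <- colnames(s) <- sprintf("S%02d", 1:n)
      g <- random_dist(n, seed = 2000 + k, kind = "geographic")
      gm <- unclass(g) * 50 + 0.1
      diag(gm) <- 0
      g <- dist_matrix(gm, kind = "geographic")
      decay_fit(dist_matrix(s, "community", "similarity"), g,
                n_perm = 0, seed = 1)$slope
    }, numeric(1L))
    expect_lt(abs(mean(slopes)), 3 * stats::sd(slopes) / sqrt(100))
  })
})

test_that("diffslope: zero difference on identical data; exhaustive oracle on 3v3 pairs", {
  with_seed(71, {
    pairs <- data.frame(distance = runif(10, 0, 2), similarity = runif(10))
    same <- diffslope(pairs, pairs, n_perm = 199, seed = 1)
    expect_equal(same$statistic, 0)
    expect_gt(same$p_value, 0.5)

    p1 <- data.frame(distance = c(0.1, 0.7, 1.3), similarity = c(0.9, 0.5, 0.2))
    p2 <- data.frame(distance = c(0.2, 0.8, 1.4), similarity = c(0.4, 0.45, 0.42))
    obs <- diffslope(p1, p2, n_perm = 2000, seed = 2)
    # enumerate all choose(6,3) membership assignments
    x <- c(p1$distance, p2$distance); y <- c(p1$similarity, p2$similarity)
    slope <- function(i) stats::cov(x[i], y[i]) / stats::var(x[i])
    combos <- utils::combn(6, 3)
    diffs <- apply(combos, 2L, function(i) slope(i) - slope(setdiff(1:6, i)))
    p_exact <- mean(abs(diffs) >= abs(obs$statistic) - 1e-12)
    se <- sqrt(p_exact * (1 - p_exact) / 2000)
    expect_lt(abs(obs$p_value - p_exact), 3 * se + 2 / 2000)
  })
})

test_that("PERMANOVA: perfect separation, R^2 bounds, vegan::adonis2 cross-check", {
  block <- function(v) matrix(v, 3, 3)
  d <- rbind(cbind(block(0), block(1)), cbind(block(1), block(0)))
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("S%d", 1:6)
  D <- dist_matrix(d, kind = "community")
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(D, g, n_perm = 199, seed = 1)
  # with perfect separation the p-value sits at its attainable floor: the
  # fraction of label permutations that reproduce the same partition
  # (those tie with the observed F)
  frac_tie <- 2 * factorial(3)^2 / factorial(6)
  expect_lt(res$p_value,
            frac_tie + 3 * sqrt(frac_tie * (1 - frac_tie) / 199) + 1 / 200)
  expect_gte(res$p_value, 1 / 200)
  expect_true(res$r2 > 0 && res$r2 <= 1)

  Dr <- random_dist(9, seed = 81)
  gr <- rep(c("x", "y", "z"), each = 3)
  ours <- permanova(Dr, gr, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(unclass(Dr)) ~ gr, permutations = 99)
  expect_equal(ours$statistic, ref$F[1L], tolerance = 1e-10)
  expect_equal(ours$r2, ref$R2[1L], tolerance = 1e-10)
  expect_error(permanova(Dr, c(gr[-1], "w"), n_perm = 9), "2 samples")
})

test_that("permutation p-values carry the +1 correction and reproduce under a seed", {
  A <- random_dist(6, seed = 91)
  B <- random_dist(6, seed = 92)
  r1 <- mantel_test(A, B, n_perm = 199, seed = 13)
  r2 <- mantel_test(A, B, n_perm = 199, seed = 13)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(r1$p_value >= 1 / 200 && r1$p_value <= 1)
  expect_true(any(abs(r1$p_value * 200 - round(r1$p_value * 200)) < 1e-9))
})
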