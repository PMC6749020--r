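# Shared fixtures: all built in code at test time.

toy_counts <- function(n = 3, m = 2, seed = 1, max_count = 50) {
  withr_seed <- function(code) soilhomog::with_seed(seed, code)
  withr_seed({
    counts <- matrix(sample.int(max_count, n * m, replace = TRUE), n, m,
                     dimnames = list(sprintf("S%02d", seq_len(n)),
                                     sprintf("OTU%03d", seq_len(m))))
    counts
  })
}

toy_metadata <- function(ids, site = "forest", molecule = "DNA") {
  data.frame(site = site, molecule = molecule,
             x = seq_along(ids), y = rev(seq_along(ids)),
             row.names = ids)
}

toy_table <- function(n = 3, m = 2, seed = 1, max_count = 50) {
  counts <- toy_counts(n, m, seed, max_count)
  community_table(counts, toy_metadata(rownames(counts)))
}

# clean negative-binomial two-group count simulator (independent of the
# package's generator; used to validate the differential-abundance test)
sim_nb_counts <- function(m, n1 = 13, n2 = 13, lfc_taxa = 0, lfc = 0,
                          seed = 1) {
  with_seed(seed, {
    mu <- stats::rlnorm(m, 3, 1.5)
    alpha <- 0.05 + 2 / mu + stats::rlnorm(m, 0, 0.3) * 0.15
    fc <- rep(1, m)
    if (lfc_taxa > 0) fc[seq_len(lfc_taxa)] <- 2^lfc
    g <- rep(c(0, 1), c(n1, n2))
    Y <- vapply(seq_len(m), function(k)
      stats::rnbinom(n1 + n2, mu = mu[k] * ifelse(g == 1, fc[k], 1),
                     size = 1 / alpha[k]), numeric(n1 + n2))
    dimnames(Y) <- list(sprintf("S%02d", seq_len(n1 + n2)),
                        sprintf("T%04d", seq_len(m)))
    list(counts = Y, groups = factor(rep(c("a", "b"), c(n1, n2))),
         true_lfc_taxa = colnames(Y)[seq_len(lfc_taxa)])
  })
}

# random symmetric dissimilarity matrix with labels
random_dist <- function(n, seed = 1, kind = "community") {
  with_seed(seed, {
    p <- matrix(runif(n * 2), n)
    d <- as.matrix(dist(p)) / sqrt(2)
    rownames(d) <- colnames(d) <- sprintf("S%02d", seq_len(n))
    dist_matrix(d, kind = kind)
  })
}

# brute-force Canberra (averaged dialect) by double loop
canberra_brute <- function(counts) {
  n <- nrow(counts)
  out <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    x <- counts[i, ]; y <- counts[j, ]
    keep <- (x + y) > 0
    out[i, j] <- sum(abs(x - y)[keep] / (x + y)[keep]) / sum(keep)
  }
  out
}

# exact Mantel p by enumerating all permutations of A's labels
mantel_exact_p <- function(A, B, tail = "greater") {
  n <- nrow(A)
  perms <- all_perms(n)
  lt <- lower.tri(A)
  bv <- B[lt]
  robs <- stats::cor(A[lt], bv)
  rs <- apply(perms, 1L, function(p) stats::cor(A[p, p][lt], bv))
  if (tail == "greater") mean(rs >= robs - 1e-12) else mean(rs <= robs + 1e-12)
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

scaled_config <- function(...) {
  args <- utils::modifyList(
    list(n_taxa = 400, depth_range = c(2000, 4000),
         rarefaction_depth = 1000, rarefaction_reps = 20,
         n_newcomers = 60, n_bloomers = 40),
    list(...))
  do.call(scenario_config, args)
}
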