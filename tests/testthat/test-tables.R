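test_that("classic TSV and BIOM round-trips preserve counts, ids and metadata", {
  tab <- toy_table(3, 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  md <- withr::local_tempfile(fileext = ".tsv")
  write_community(tab, tsv, metadata_path = md)
  back <- read_community(tsv, md)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$metadata$site, tab$metadata$site)
  expect_equal(back$metadata$x, tab$metadata$x)

  skip_if_not_installed("biomformat")
  biom <- withr::local_tempfile(fileext = ".biom")
  write_community(tab, biom, format = "biom")
  back2 <- read_community(biom, md, format = "biom")
  expect_equal(back2$counts[rownames(tab$counts), colnames(tab$counts)],
               tab$counts)
})

test_that("constructor contracts: missing metadata sample is named; negatives refused", {
  counts <- toy_counts(3, 2)
  md <- toy_metadata(rownames(counts)[1:2])
  expect_error(community_table(counts, md), "S03")
  bad <- counts; bad[1, 1] <- -1
  expect_error(community_table(bad, toy_metadata(rownames(counts))), "negative")
})

test_that("rarefy_once conserves depth, handles exhaustive and single-support draws", {
  tab <- toy_table(4, 6, seed = 3, max_count = 200)
  depth <- 100
  r <- rarefy_once(tab, depth, seed = 11)
  expect_true(all(rowSums(r$counts) == depth))
  # exhaustive draw returns the row unchanged
  full <- rarefy_once(tab, min(rowSums(tab$counts)), seed = 1)
  i <- which.min(rowSums(tab$counts))
  expect_equal(full$counts[i, ], tab$counts[i, ])
  # all mass on one taxon
  one <- community_table(matrix(c(100, 0), 1, 2,
                                dimnames = list("S1", c("A", "B"))),
                         toy_metadata("S1"))
  expect_equal(unname(rarefy_once(one, 50, seed = 2)$counts[1, ]), c(50, 0))
  expect_error(rarefy_once(tab, 0), "positive")
})

test_that("samples below depth are dropped with a warning, not an error", {
  counts <- rbind(S1 = c(30, 30), S2 = c(2, 1))
  colnames(counts) <- c("A", "B")
  tab <- community_table(counts, toy_metadata(rownames(counts)))
  expect_warning(r <- rarefy_once(tab, 10, seed = 1), "S2")
  expect_equal(rownames(r$counts), "S1")
})

test_that("rarefaction averaging: degenerate mean, reproducibility, depth conservation", {
  tab <- toy_table(4, 6, seed = 5, max_count = 300)
  a1 <- rarefaction_average(tab, 50, n_reps = 1, seed = 42)
  r1 <- rarefy_once(tab, 50, seed = 42)
  expect_equal(a1$counts, r1$counts)
  a <- rarefaction_average(tab, 50, n_reps = 10, seed = 9)
  expect_true(all(abs(rowSums(a$counts) - 50) < 1e-6))
  b <- rarefaction_average(tab, 50, n_reps = 10, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_error(rarefaction_average(tab, 50, n_reps = 0), "n_reps")
})

test_that("rarefaction average converges to the hypergeometric expectation", {
  counts <- toy_counts(5, 5, seed = 8, max_count = 60)
  tab <- community_table(counts, toy_metadata(rownames(counts)))
  depth <- floor(min(rowSums(counts)) * 0.8)
  n_reps <- 1000
  avg <- rarefaction_average(tab, depth, n_reps = n_reps, seed = 123)
  rs <- rowSums(counts)
  expected <- depth * counts / rs
  # per-entry SE of the mean of n_reps hypergeometric draws
  p <- counts / rs
  se <- sqrt(depth * p * (1 - p) * ((rs - depth) / (rs - 1))) / sqrt(n_reps)
  dev <- abs(avg$counts - expected)
  expect_true(all(dev <= 3 * se + 1e-9))
})

test_that("richness counts detected taxa above the threshold", {
  counts <- rbind(S1 = c(0, 0, 0), S2 = c(1, 0, 2), S3 = c(5, 5, 5))
  colnames(counts) <- sprintf("T%d", 1:3)
  tab <- community_table(counts, toy_metadata(rownames(counts)))
  expect_equal(unname(richness(tab)), c(0, 2, 3))
  expect_equal(unname(richness(tab, detection_threshold = 1)), c(0, 1, 3))
})

test_that("taxonomic aggregation sums ranks, normalizes, and pools unmapped taxa", {
  counts <- rbind(S1 = c(3, 4, 2), S2 = c(1, 1, 1))
  colnames(counts) <- c("otuA", "otuB", "otuC")
  tab <- community_table(counts, toy_metadata(rownames(counts)))
  map <- c(otuA = "Acidobacteria", otuB = "Acidobacteria")
  expect_warning(agg <- aggregate_taxonomy(tab, map), "1 unmapped")
  expect_equal(unname(agg$counts["S1", "Acidobacteria"]), 7)
  expect_equal(unname(agg$counts["S1", "Unassigned"]), 2)
  rel <- suppressWarnings(aggregate_taxonomy(tab, map, relative = TRUE))
  expect_equal(unname(rowSums(rel$counts)), c(1, 1))
  expect_error(aggregate_taxonomy(tab, c(zzz = "X")), "no taxon")
})
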