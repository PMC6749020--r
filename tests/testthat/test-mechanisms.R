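mk_avg_table <- function(counts) {
  community_table(counts, toy_metadata(rownames(counts)))
}

test_that("newcomers are the target-detected taxa absent from every reference sample", {
  ref <- mk_avg_table(rbind(S1 = c(A = 3, B = 1, C = 0, D = 0),
                            S2 = c(A = 1, B = 0, C = 0, D = 0)))
  tgt <- mk_avg_table(rbind(S3 = c(A = 2, B = 0, C = 4, D = 1),
                            S4 = c(A = 0, B = 0, C = 1, D = 0)))
  nc <- identify_newcomers(tgt, ref)
  expect_setequal(nc$taxa, c("C", "D"))
  # subset target -> empty set
  sub <- mk_avg_table(rbind(S3 = c(A = 2, B = 1, C = 0, D = 0),
                            S4 = c(A = 1, B = 0, C = 0, D = 0)))
  expect_length(identify_newcomers(sub, ref)$taxa, 0)
  # strict rule: demand presence in >= 5 of 100 rarefactions
  tgt2 <- mk_avg_table(rbind(S3 = c(A = 2, B = 0, C = 0.02, D = 1),
                             S4 = c(A = 0, B = 0, C = 0.01, D = 0)))
  strict <- identify_newcomers(tgt2, ref, min_reps = 5, n_reps = 100)
  expect_setequal(strict$taxa, "D")
})

test_that("occurrence frequency counts detected samples and averages over the set", {
  counts <- matrix(0, 13, 2, dimnames = list(sprintf("S%02d", 1:13),
                                             c("A", "B")))
  counts[1:3, "A"] <- 5
  counts[, "B"] <- 1
  tab <- mk_avg_table(counts)
  of <- occurrence_frequency(tab, c("A", "B"))
  expect_equal(unname(of$freq["A"]), 3 / 13, tolerance = 1e-12)
  expect_equal(round(unname(of$freq["A"]), 4), 0.2308)
  expect_equal(unname(of$freq["B"]), 1)
  expect_equal(of$mean, mean(c(3 / 13, 1)))
})

test_that("bloomers require positive fold change, BH significance, and reference presence", {
  d <- sim_nb_counts(150, 13, 13, lfc_taxa = 30, lfc = 2.5, seed = 55)
  ref_counts <- d$counts[d$groups == "a", ]
  tgt_counts <- d$counts[d$groups == "b", ]
  ref <- community_table(ref_counts, toy_metadata(rownames(ref_counts)))
  tgt <- community_table(tgt_counts, toy_metadata(rownames(tgt_counts)))
  bl <- suppressWarnings(identify_bloomers(tgt, ref))
  expect_gte(length(intersect(bl$taxa, d$true_lfc_taxa)),
             0.6 * length(d$true_lfc_taxa))
  da <- attr(bl, "diffabund")$results
  kept <- da[match(bl$taxa, da$taxon), ]
  expect_true(all(kept$log2FoldChange > 0 & kept$padj < 0.05))
  # reversed enrichment direction yields an empty set
  bl_rev <- suppressWarnings(identify_bloomers(ref, tgt))
  expect_length(intersect(bl_rev$taxa, d$true_lfc_taxa), 0)
})

test_that("removal analysis: empty set is the identity; removing everything errors", {
  cfg <- scaled_config(n_taxa = 120)
  sim <- suppressWarnings(simulate_scenario("pristine", cfg, seed = 61))
  ra <- removal_analysis(sim$target$dna, character(), depth = 1000,
                         n_reps = 5, n_perm = 49, seed = 3)
  expect_equal(ra$before$similarity$mean, ra$after$similarity$mean)
  expect_equal(ra$before$decay$slope, ra$after$decay$slope)
  expect_error(removal_analysis(sim$target$dna, taxon_ids(sim$target$dna),
                                depth = 1000, n_reps = 5, seed = 3),
               "every taxon")
})

test_that("removal analysis lowers the depth when removal starves a sample", {
  counts <- rbind(S1 = c(A = 60, B = 40, C = 900),
                  S2 = c(A = 80, B = 20, C = 1100),
                  S3 = c(A = 30, B = 80, C = 800),
                  S4 = c(A = 50, B = 50, C = 700))
  tab <- community_table(counts, toy_metadata(rownames(counts)))
  expect_warning(ra <- removal_analysis(tab, "C", depth = 1000, n_reps = 3,
                                        n_perm = 9, seed = 1),
                 "lowering depth")
  expect_equal(ra$depth, 100)
})

test_that("mechanism report attributes a bloom to bloomers with newcomers cleared", {
  cfg <- scaled_config()
  sim <- suppressWarnings(simulate_scenario("bloom", cfg, seed = 101))
  rep <- suppressWarnings(
    mechanism_report(sim$forest, sim$target, depth = 1000, n_reps = 20,
                     n_perm = 199, seed = 7))
  expect_true(rep$dna$bloomers_verdict$contributes)
  expect_true(rep$rna$bloomers_verdict$contributes)
  expect_false(rep$dna$newcomers_verdict$contributes)
  expect_false(rep$rna$newcomers_verdict$contributes)
  # the field signature of a range expansion: bloomers are more
  # widespread where they bloomed than in the forest
  expect_gt(rep$dna$bloomers$freq_target$mean,
            rep$dna$bloomers$freq_reference$mean)
  # serialization round trip of the summary table
  json <- withr::local_tempfile(fileext = ".json")
  write_mechanism_report(rep, json)
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(nrow(parsed$summary), 4L)
  expect_true(file.exists(sub("\\.json$", ".tsv", json)))
})
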