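test_that("nested grid: 13 distinct points with the documented extremes and shared corner", {
  coords <- nested_coords()
  expect_equal(nrow(coords), 13L)
  expect_equal(nrow(unique(coords)), 13L)
  d <- as.matrix(dist(coords))
  off <- d[lower.tri(d)]
  expect_equal(min(off), 0.1)
  expect_equal(max(off), 100 * sqrt(2))
  # the origin corner is shared by every quadrat: its 3 non-shared corners
  # per nested quadrat all touch (0,0) at distance quadrat*sqrt(2) or less
  expect_true(all(c(0, 0) %in% unlist(coords[1, ])))
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- scaled_config(n_taxa = 100)
  s1 <- suppressWarnings(simulate_scenario("bloom", cfg, seed = 5))
  s2 <- suppressWarnings(simulate_scenario("bloom", cfg, seed = 5))
  expect_identical(s1$forest$rna$counts, s2$forest$rna$counts)
  expect_identical(s1$target$dna$counts, s2$target$dna$counts)
  expect_identical(s1$bloomer_ids, s2$bloomer_ids)
  s3 <- suppressWarnings(simulate_scenario("bloom", cfg, seed = 6))
  expect_false(identical(s1$target$dna$counts, s3$target$dna$counts))
})

test_that("row sums equal the drawn depths and fall inside the configured range", {
  cfg <- scaled_config(n_taxa = 150)
  sim <- suppressWarnings(simulate_scenario("pristine", cfg, seed = 9))
  for (tab in list(sim$forest$rna, sim$forest$dna, sim$target$rna)) {
    rs <- rowSums(tab$counts)
    expect_true(all(rs >= cfg$depth_range[1] & rs <= cfg$depth_range[2]))
  }
})

test_that("with no relic pool and unit coupling the RNA and DNA layers share a composition", {
  cfg <- scaled_config(n_taxa = 120, relic_fraction = 0, coupling = 1,
                       active_fraction = 1)
  coords <- nested_coords(cfg)
  env <- simulate_environment(coords, cfg, seed = 2)
  with_seed(3, {
    traits <- soilhomog:::draw_taxon_traits(cfg)
    presence <- soilhomog:::draw_presence(coords, traits, cfg$occupancy_range)
    comp <- soilhomog:::expected_compositions(scale(env$values[, 1])[, 1],
                                              traits, presence, cfg)
    expect_equal(comp$rna, comp$dna, tolerance = 1e-12)
    expect_equal(unname(rowSums(comp$rna)), rep(1, 13))
  })
})

test_that("environment: spatial structure in the forest, broken and inflated by disturbance", {
  cfg <- scaled_config()
  coords <- nested_coords(cfg)
  geo <- geographic(coords)
  hits <- 0; var_up <- 0; sim_down <- 0
  n_rep <- 12
  for (k in seq_len(n_rep)) {
    env_f <- simulate_environment(coords, cfg, seed = 600 + k)
    m <- mantel_test(gower_similarity(env_f), geo, n_perm = 99, seed = 1)
    hits <- hits + (m$p_value < 0.05)
    env_d <- simulate_environment(coords, cfg,
                                  disturbance = cfg$disturbance_mult,
                                  base_env = env_f, seed = 700 + k)
    var_up <- var_up + (mean(apply(env_d$values, 2, var)) >
                          mean(apply(env_f$values, 2, var)))
    sim_down <- sim_down +
      (mean_pairwise_similarity(gower_similarity(env_d))$mean <
         mean_pairwise_similarity(gower_similarity(env_f))$mean)
  }
  expect_gte(hits, n_rep - 2)      # forest fields decay with distance
  expect_equal(var_up, n_rep)      # disturbance adds variance
  expect_gte(sim_down, n_rep - 1)  # and lowers environmental similarity
})

test_that("invasion: injected taxa are novel, recovered, and hold the configured share", {
  cfg <- scaled_config(n_taxa = 200)
  sim <- suppressWarnings(simulate_scenario("invasion_strong", cfg, seed = 21))
  expect_length(sim$newcomer_ids, cfg$n_newcomers)
  # absent from the forest by construction
  expect_true(all(colSums(sim$forest$rna$counts[, sim$newcomer_ids]) == 0))
  expect_true(all(colSums(sim$forest$dna$counts[, sim$newcomer_ids]) == 0))
  # depths preserved by the count reshuffle
  expect_true(all(rowSums(sim$target$rna$counts) >= cfg$depth_range[1]))
  # collective share close to the configured 25% (strong preset)
  rel <- sim$target$dna$counts / rowSums(sim$target$dna$counts)
  share <- sum(colMeans(rel[, sim$newcomer_ids]))
  expect_lt(abs(share - 0.25) / 0.25, 0.2)
  # newcomer recovery through the standard detection rule
  f_avg <- rarefaction_average(sim$forest$dna, 1000, 10, seed = 1)
  t_avg <- rarefaction_average(sim$target$dna, 1000, 10, seed = 2)
  found <- identify_newcomers(t_avg, f_avg)
  expect_gte(length(intersect(found$taxa, sim$newcomer_ids)),
             0.95 * length(sim$newcomer_ids))
})

test_that("invasion and bloom leave tables untouched in their identity configurations", {
  cfg <- scaled_config(n_taxa = 100)
  sim <- suppressWarnings(simulate_scenario("pristine", cfg, seed = 31))
  same <- apply_invasion(sim$target, n_newcomers = 0,
                         injection_rel_abund = 0.1, occupancy = 0.5, seed = 1)
  expect_identical(same$rna$counts, sim$target$rna$counts)
  expect_error(apply_invasion(sim$target, 5, 0.1, occupancy = 0, seed = 1),
               "occupancy")
  same2 <- apply_bloom(sim$target, candidates = taxon_ids(sim$target$dna),
                       n_bloomers = 10, fold = 1, homogenize = 0, seed = 1)
  expect_identical(same2$dna$counts, sim$target$dna$counts)
  expect_error(apply_bloom(sim$target, candidates = c("OTU0001", "OTU0002"),
                           n_bloomers = 10, fold = 2), "fewer candidate")
})

test_that("bloom scenario carries the homogenization signature", {
  cfg <- scaled_config()
  up <- 0
  for (k in 1:5) {
    sim <- suppressWarnings(simulate_scenario("bloom", cfg, seed = 40 + k))
    f <- rarefaction_average(sim$forest$dna, 1000, 10, seed = 1)
    t <- rarefaction_average(sim$target$dna, 1000, 10, seed = 1)
    up <- up + (mean_pairwise_similarity(canberra(t))$mean >
                  mean_pairwise_similarity(canberra(f))$mean)
  }
  expect_gte(up, 4)
})
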