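# Spatially explicit generator of paired RNA/DNA soil communities.
#
# The generator emulates the sampling design and statistical structure the
# analysis pipeline assumes: a nested quadrat grid of 13 points per site,
# a spatially autocorrelated soil environment that loses spatial structure
# (but gains variance) under conversion, log-normal taxon abundances with
# Gaussian niche filtering along one environmental axis, an RNA layer
# enriched for environment-responsive (active) taxa, a DNA layer that
# additionally carries a spatially flat inactive/relic pool, and optional
# injected "newcomer" taxa and fold-amplified "bloomer" taxa.

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe the baseline study conditions: a 100 m plot with
#' 10/1/0.1 m nested quadrats (13 samples per site), 2000 taxa with
#' log-normal abundance (sigma = 1.5) and Gaussian niches on the first
#' environmental axis, 7 soil variables with exponential spatial
#' covariance, sequencing depths uniform on 5000-20000, rarefaction depth
#' 3790, an active fraction of 0.6 with RNA niche coupling 1.5, a DNA
#' relic fraction of 0.35, and conversion effects of 150 newcomers at a 2%
#' collective share, 50 bloomers at a median 4-fold, and an environmental
#' disturbance multiplier of 4.
#'
#' @param n_taxa number of taxa in the regional pool.
#' @param plot_size plot edge in meters.
#' @param quadrat_sizes strictly decreasing nested quadrat edges (m).
#' @param lognormal_sigma heavy-tail parameter of taxon base abundances.
#' @param niche_width mean Gaussian niche width on the standardized
#'   environmental axis (per-taxon widths are uniform on 0.5-1.5 times this).
#' @param env_range range (m) of the exponential spatial covariance of the
#'   environment.
#' @param env_nugget nugget variance of the environment.
#' @param n_env_vars number of soil variables (the first is the niche axis;
#'   the rest are correlated nuisance axes).
#' @param disturbance_mult standard deviation, relative to the field, of the
#'   independent per-sample noise added to each variable in disturbed
#'   scenarios (0 = undisturbed).
#' @param active_fraction fraction of taxa that are active (enter the RNA
#'   layer).
#' @param coupling environmental niche-coupling multiplier (>= 1) applied to
#'   the RNA layer's niche kernel.
#' @param relic_fraction mixture weight of the spatially flat relic/inactive
#'   pool in the DNA layer.
#' @param depth_range min/max sequencing depth per sample.
#' @param low_depth_prob probability a sample draws a shallow depth below
#'   the rarefaction depth (exercises sample dropping; default 0).
#' @param low_depth_range depth range for such shallow samples.
#' @param rarefaction_depth target depth used downstream.
#' @param rarefaction_reps number of rarefactions averaged downstream.
#' @param n_newcomers,injection_rel_abund,invasion_occupancy invasion
#'   effect: number of injected taxa, their *collective* expected community
#'   share (default 0.02, the few-percent share newly arrived taxa
#'   typically hold), and the fraction of samples each occupies (default
#'   0.25; newly arrived taxa are geographically narrow, occurring in
#'   about a quarter of samples).
#' @param n_bloomers,bloom_fold,bloom_homogenize bloom effect: number of
#'   amplified resident taxa, their fold amplification, and the weight with
#'   which a blooming taxon's expected profile is pulled toward a spatially
#'   even one. A bloom is a release from local constraints -- the taxon
#'   grows wherever resources appear -- so its expected count in sample i
#'   becomes `fold * ((1 - h) * c_i + h * typical)` with `typical` its
#'   median positive count. The default h = 0.75 reproduces the observed
#'   signature of converted-site bloomers: occurrence frequency rising from
#'   roughly half the samples to most of them.
#' @param occupancy_beta shape parameters of the Beta distribution of
#'   per-taxon microsite occupancy: soil taxa are patchy at the plot scale,
#'   so each taxon occupies only a (taxon-specific) subset of samples
#'   irrespective of its niche match.
#' @param occupancy_range correlation range (m) of the occupancy patches:
#'   a taxon's presences are aggregated at the sub-meter microsite scale
#'   (default 1 m), so patchiness adds noise but carries little of the
#'   plot-scale distance-decay, which flows through the environment.
#' @param disturbed_occupancy_range optional occupancy correlation range
#'   after disturbance: set a range to additionally redraw the patch
#'   structure of disturbed sites (churned soil); the default `NA` keeps
#'   the site's patch structure and lets disturbance act through the
#'   environment alone.
#' @param relic_noise log-scale standard deviation of the per-sample noise
#'   of the relic pool composition (the relic pool is shared in
#'   expectation but heterogeneous sample to sample).
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_taxa = 2000,
                            plot_size = 100,
                            quadrat_sizes = c(10, 1, 0.1),
                            lognormal_sigma = 1.5,
                            niche_width = 1.5,
                            env_range = 50,
                            env_nugget = 0.05,
                            n_env_vars = 7,
                            disturbance_mult = 4,
                            active_fraction = 0.6,
                            coupling = 1.5,
                            relic_fraction = 0.35,
                            depth_range = c(5000, 20000),
                            low_depth_prob = 0,
                            low_depth_range = c(500, 3000),
                            rarefaction_depth = 3790,
                            rarefaction_reps = 100,
                            n_newcomers = 150,
                            injection_rel_abund = 0.02,
                            invasion_occupancy = 0.25,
                            n_bloomers = 50,
                            bloom_fold = 4,
                            bloom_homogenize = 0.75,
                            occupancy_beta = c(2, 1),
                            occupancy_range = 1,
                            disturbed_occupancy_range = NA,
                            relic_noise = 1) {
  cfg <- as.list(environment())
  stopifnot(all(diff(cfg$quadrat_sizes) < 0),
            cfg$coupling >= 1, cfg$bloom_fold >= 1,
            cfg$relic_fraction >= 0, cfg$relic_fraction <= 1,
            cfg$active_fraction > 0, cfg$active_fraction <= 1,
            cfg$injection_rel_abund >= 0, cfg$injection_rel_abund < 1,
            cfg$low_depth_prob >= 0, cfg$low_depth_prob <= 1)
  structure(cfg, class = "scenario_config")
}

#' Nested-grid sampling coordinates
#'
#' Corners of the full plot quadrat (4 points) plus, for each nested
#' quadrat anchored at the origin corner, its 3 corners not shared with the
#' larger quadrats: 13 distinct points for the default 100/10/1/0.1 m
#' design.
#'
#' @param config a [scenario_config()].
#' @return data.frame with columns `x`, `y` (meters) and sample row names.
#' @export
nested_coords <- function(config = scenario_config()) {
  p <- config$plot_size
  pts <- rbind(c(0, 0), c(p, 0), c(0, p), c(p, p))
  for (q in config$quadrat_sizes)
    pts <- rbind(pts, c(q, 0), c(0, q), c(q, q))
  coords <- data.frame(x = pts[, 1L], y = pts[, 2L])
  rownames(coords) <- sprintf("S%02d", seq_len(nrow(coords)))
  coords
}

# disturbance = spatially unstructured per-sample shock shared across
# variables (patchy disturbance intensity drives the soil chemistry
# jointly) plus smaller variable-specific noise
disturbance_noise <- function(n, k, disturbance) {
  outer(rnorm(n, sd = disturbance), rep(1, k)) +
    matrix(rnorm(n * k, sd = 0.4 * disturbance), n, k)
}

#' Simulate a spatially structured soil environment
#'
#' Each variable is a Gaussian random field over the sample coordinates
#' with exponential covariance `exp(-d / range)` plus a nugget. The first
#' variable is the niche axis; later variables are mixtures of the niche
#' axis and independent fields (two of them strongly collinear with it, to
#' exercise variable pruning). Disturbance adds independent per-sample
#' noise to every variable, which destroys the spatial structure while
#' increasing total variance. Variables are affinely rescaled to
#' chemistry-like units.
#'
#' @param coords data.frame of sample coordinates (see [nested_coords()]).
#' @param config a [scenario_config()].
#' @param disturbance noise multiplier; defaults to 0 (the undisturbed,
#'   forest condition). Use `config$disturbance_mult` for converted sites.
#' @param base_env optional [env_table()] from a previous call: instead of
#'   drawing a fresh field, the disturbance noise is layered onto this
#'   existing environment (conversion disturbs the *same* place).
#' @param seed optional integer seed.
#' @return an [env_table()] (attribute `"var_scale"` records per-variable
#'   scales so disturbance noise stays proportionate).
#' @export
simulate_environment <- function(coords, config = scenario_config(),
                                 disturbance = 0, base_env = NULL,
                                 seed = NULL) {
  stopifnot(config$env_range > 0)
  if (!is.null(base_env)) {
    vs <- attr(base_env, "var_scale")
    if (is.null(vs)) stopf("base_env must come from simulate_environment()")
    return(with_seed(seed, {
      vals <- base_env$values
      if (disturbance > 0)
        vals <- vals + disturbance_noise(nrow(vals), ncol(vals), disturbance) %*%
          diag(vs, length(vs))
      out <- env_table(vals)
      attr(out, "var_scale") <- vs
      out
    }))
  }
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  Sigma <- exp(-d / config$env_range) + diag(config$env_nugget, n)
  # (disturbance noise, used below, is mostly a shared per-sample shock:
  # burn intensity is patchy in space but moves the chemistry jointly)
  L <- tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(1e-8, n))  # jitter for numerical PD
  })
  k <- config$n_env_vars
  with_seed(seed, {
    fields <- t(L) %*% matrix(rnorm(n * (k + 1L)), n, k + 1L)
    niche <- fields[, 1L]
    # mixing weights with the niche axis: two near-collinear nuisance
    # variables, the rest progressively more independent
    rho <- c(1, 0.9, 0.85, seq(0.4, 0.05, length.out = max(k - 3L, 1L)))[seq_len(k)]
    vals <- sapply(seq_len(k), function(j)
      rho[j] * niche + sqrt(1 - rho[j]^2) * fields[, j + 1L])
    if (disturbance > 0)
      vals <- vals + disturbance_noise(n, k, disturbance)
    # chemistry-flavoured units (Gower is range-normalized, so affine
    # rescaling is cosmetic)
    center <- c(5.2, 4.1, 25, 80, 11, 9, 14)[seq_len(k)]
    scale <- c(0.5, 1.5, 9, 25, 2.5, 4, 5)[seq_len(k)]
    center[is.na(center)] <- 0; scale[is.na(scale)] <- 1
    vals <- sweep(sweep(vals, 2L, scale, "*"), 2L, center, "+")
    nm <- c("pH", "organic_matter", "P", "K", "CEC", "nitrate_N", "S")
    colnames(vals) <- if (k <= 7L) nm[seq_len(k)] else
      c(nm, sprintf("V%d", seq_len(k - 7L)))
    rownames(vals) <- rownames(coords)
    out <- env_table(vals)
    attr(out, "var_scale") <- scale
    out
  })
}

# expected composition matrices (samples x taxa), given traits and the
# 0/1 microsite presence mask; the relic pool (dead-cell DNA) is only
# weakly spatially coupled: a shared heavy-tailed base composition with
# independent per-sample noise, unmasked and blind to the niche axis
expected_compositions <- function(env_axis, traits, presence, config) {
  kern <- exp(-outer(env_axis, traits$optimum, "-")^2 /
              (2 * matrix(traits$width^2, length(env_axis),
                          nrow(traits), byrow = TRUE)))
  rna_w <- sweep(kern^config$coupling, 2L,
                 traits$abundance * traits$active, "*") * presence
  rna <- rna_w / rowSums(rna_w)
  cell_w <- sweep(kern, 2L, traits$abundance, "*") * presence
  cell <- cell_w / rowSums(cell_w)
  relic_w <- matrix(traits$relic_weight, nrow(rna), ncol(rna), byrow = TRUE) *
    exp(matrix(rnorm(length(rna), 0, config$relic_noise), nrow(rna)))
  relic <- relic_w / rowSums(relic_w)
  dna <- (1 - config$relic_fraction) * rna + config$relic_fraction * relic
  list(rna = rna, dna = dna)
}

draw_taxon_traits <- function(config) {
  k <- config$n_taxa
  active <- rbinom(k, 1L, config$active_fraction)
  if (!any(active == 1L)) active[1L] <- 1L
  list2DF(list(
    optimum = runif(k, -2.5, 2.5),
    width = runif(k, 0.5, 1.5) * config$niche_width,
    abundance = rlnorm(k, 0, config$lognormal_sigma),
    active = active,
    relic_weight = rlnorm(k, 0, config$lognormal_sigma),
    occupancy = stats::rbeta(k, config$occupancy_beta[1L],
                             config$occupancy_beta[2L])))
}

# spatially aggregated microsite occupancy: each taxon's presence comes
# from thresholding its own short-range Gaussian field at its occupancy
# quantile, so patches are coherent over ~occupancy_range meters
draw_presence <- function(coords, traits, range_m) {
  n <- nrow(coords)
  k <- nrow(traits)
  Sigma <- exp(-as.matrix(dist(coords)) / range_m) + diag(1e-6, n)
  z <- t(chol(Sigma)) %*% matrix(rnorm(n * k), n, k)
  m <- (z < matrix(qnorm(traits$occupancy), n, k, byrow = TRUE)) * 1
  # every taxon occupies at least one sample
  m[cbind(sample.int(n, k, replace = TRUE), seq_len(k))] <- 1
  m
}

draw_depths <- function(n, config) {
  lo <- runif(n) < config$low_depth_prob
  d <- round(runif(n, config$depth_range[1L], config$depth_range[2L]))
  d[lo] <- round(runif(sum(lo), config$low_depth_range[1L],
                       config$low_depth_range[2L]))
  d
}

make_site_table <- function(comp, depths, coords, site, molecule, taxa) {
  counts <- t(sapply(seq_len(nrow(comp)), function(i)
    rmultinom(1L, depths[i], comp[i, ])[, 1L]))
  dimnames(counts) <- list(rownames(coords), taxa)
  md <- data.frame(site = site, molecule = molecule,
                   x = coords$x, y = coords$y, row.names = rownames(coords))
  community_table(counts, md)
}

#' Simulate paired RNA/DNA community tables for one site
#'
#' Expected relative abundance of taxon k in sample i is proportional to a
#' log-normal base abundance times a Gaussian niche kernel on the first
#' environmental axis. The RNA layer draws from the active taxa with the
#' niche kernel raised to the coupling power (active taxa track the
#' environment more tightly); the DNA layer draws from a mixture of that
#' same composition and a spatially flat relic/inactive pool. Counts are
#' multinomial at per-sample depths.
#'
#' @param env an [env_table()] for the site (first column = niche axis).
#' @param coords sample coordinates (rows aligned with `env`).
#' @param config a [scenario_config()].
#' @param site site label stored in the metadata.
#' @param traits optional taxon traits (to reuse one regional pool across
#'   sites); drawn from `config` when `NULL`.
#' @param presence optional 0/1 samples x taxa microsite occupancy mask
#'   (to model re-sampling the same stand); drawn from the taxon occupancy
#'   probabilities when `NULL`.
#' @param seed optional integer seed.
#' @return list with `rna` and `dna` ([community_table()]s of raw counts),
#'   the `traits` used, and the `presence` mask.
#' @export
simulate_community <- function(env, coords, config = scenario_config(),
                               site = "site", traits = NULL, presence = NULL,
                               seed = NULL) {
  with_seed(seed, {
    if (is.null(traits)) traits <- draw_taxon_traits(config)
    if (is.null(presence))
      presence <- draw_presence(coords, traits, config$occupancy_range)
    axis <- scale(env$values[, 1L])[, 1L]
    comp <- expected_compositions(axis, traits, presence, config)
    if (any(rowSums(comp$rna) == 0) || any(rowSums(comp$dna) == 0))
      stopf("degenerate all-zero expected composition")
    taxa <- sprintf("OTU%04d", seq_len(config$n_taxa))
    depths_rna <- draw_depths(nrow(coords), config)
    depths_dna <- draw_depths(nrow(coords), config)
    list(rna = make_site_table(comp$rna, depths_rna, coords, site, "RNA", taxa),
         dna = make_site_table(comp$dna, depths_dna, coords, site, "DNA", taxa),
         traits = traits, presence = presence)
  })
}

#' Inject newcomer taxa into a site's tables
#'
#' Adds novel taxon columns, absent from any reference table by
#' construction, occupying a random fraction of samples and holding a
#' stated collective share of each occupied sample's counts. Existing
#' counts are down-subsampled (without replacement) so row sums (depths)
#' are preserved exactly.
#'
#' @param tables list with `rna` and `dna` [community_table()]s.
#' @param n_newcomers number of injected taxa.
#' @param injection_rel_abund collective expected relative abundance of all
#'   newcomers in an occupied sample.
#' @param occupancy fraction of samples each newcomer occupies (> 0).
#' @param seed optional integer seed.
#' @return the modified `tables` list (plus `newcomer_ids`).
#' @export
apply_invasion <- function(tables, n_newcomers, injection_rel_abund,
                           occupancy, seed = NULL) {
  if (n_newcomers == 0L) return(tables)
  if (occupancy <= 0) stopf("occupancy must be positive")
  with_seed(seed, {
    ids <- sprintf("NEW%03d", seq_len(n_newcomers))
    n <- nrow(tables$rna$counts)
    occ <- matrix(runif(n * n_newcomers) < occupancy, n, n_newcomers)
    occ[cbind(sample.int(n, n_newcomers, replace = TRUE),
              seq_len(n_newcomers))] <- TRUE  # every newcomer lands somewhere
    per_taxon_share <- injection_rel_abund / n_newcomers
    for (mol in c("rna", "dna")) {
      tab <- tables[[mol]]
      depths <- rowSums(tab$counts)
      newcols <- matrix(0, n, n_newcomers, dimnames = list(rownames(tab$counts), ids))
      for (i in seq_len(n)) {
        k_occ <- which(occ[i, ])
        if (!length(k_occ)) next
        newcols[i, k_occ] <- rbinom(length(k_occ), depths[i], per_taxon_share)
      }
      keep_depth <- depths - rowSums(newcols)
      shrunk <- t(sapply(seq_len(n), function(i)
        rarefy_row(tab$counts[i, ], keep_depth[i])))
      dimnames(shrunk) <- dimnames(tab$counts)
      tables[[mol]] <- community_table(cbind(shrunk, newcols), tab$metadata)
    }
    tables$newcomer_ids <- ids
    tables
  })
}

#' Amplify bloomer taxa in a site's tables
#'
#' Picks `n_bloomers` resident taxa (from the supplied candidate set,
#' typically taxa detected in the forest site), amplifies each by `fold`
#' while pulling its expected spatial profile toward a uniform one
#' (`homogenize` mixing weight; a blooming taxon grows wherever resources
#' appear, decoupling from its former microsite pattern), and redraws each
#' sample multinomially at its original depth from the adjusted
#' expectation. The amplification raises both the bloomers' collective
#' share and their occurrence frequency, the two field signatures of a
#' range expansion.
#'
#' @param tables list with `rna` and `dna` [community_table()]s.
#' @param candidates character vector of taxa eligible to bloom (e.g. taxa
#'   detected in the forest reference).
#' @param n_bloomers number of amplified taxa.
#' @param fold amplification factor (>= 1).
#' @param homogenize weight in \[0,1\] of the spatially even profile in the
#'   bloomed expectation (0 = pure multiplication).
#' @param fold_sdlog log-scale spread of per-taxon folds around `fold`
#'   (blooms are heterogeneous: a few strong responders expand manyfold
#'   while others barely double); 0 gives every bloomer the same fold.
#' @param seed optional integer seed.
#' @return the modified `tables` list (plus `bloomer_ids` and
#'   `bloomer_folds`).
#' @export
apply_bloom <- function(tables, candidates, n_bloomers, fold,
                        homogenize = 0.75, fold_sdlog = 0.6, seed = NULL) {
  stopifnot(fold >= 1, homogenize >= 0, homogenize <= 1)
  if (n_bloomers == 0L || (fold == 1 && homogenize == 0)) return(tables)
  if (length(candidates) < n_bloomers)
    stopf("fewer candidate taxa (%d) than requested bloomers (%d)",
          length(candidates), n_bloomers)
  with_seed(seed, {
    bloomers <- sample(candidates, n_bloomers)
    folds <- pmax(fold * exp(rnorm(n_bloomers, 0, fold_sdlog)), 1)
    names(folds) <- bloomers
    for (mol in c("rna", "dna")) {
      tab <- tables[[mol]]
      depths <- rowSums(tab$counts)
      expected <- tab$counts
      for (b in bloomers) {
        col <- expected[, b]
        typical <- if (any(col > 0)) median(col[col > 0]) else 1
        expected[, b] <- folds[[b]] *
          ((1 - homogenize) * col + homogenize * typical)
      }
      counts <- t(sapply(seq_len(nrow(expected)), function(i)
        rmultinom(1L, depths[i], expected[i, ])[, 1L]))
      dimnames(counts) <- dimnames(tab$counts)
      tables[[mol]] <- community_table(counts, tab$metadata)
    }
    tables$bloomer_ids <- bloomers
    tables$bloomer_folds <- folds
    tables
  })
}

#' Simulate a full two-site scenario
#'
#' Builds a forest (undisturbed) site and a converted-site counterpart
#' sharing the same regional taxon pool, under one of the named scenarios.
#' Non-disturbance scenarios keep the forest's environmental field for the
#' target site (same place, fresh community sampling), so each conversion
#' mechanism acts alone; disturbance scenarios layer independent
#' per-sample noise onto that same field.
#'
#' * `"pristine"` -- a forest replicate (null scenario: same environment,
#'   independent community draw);
#' * `"disturbed"` -- environmental disturbance only;
#' * `"invasion"` -- pristine environment plus injected newcomers at the
#'   config's default (paper-calibrated, ~2% share) intensity;
#' * `"invasion_strong"` -- newcomers injected at a high, detectable
#'   intensity (collective share 0.25, full occupancy): the condition under
#'   which invasion is expected to be mechanistically attributable;
#' * `"bloom"` -- fold-amplification of resident (forest-detected) taxa;
#' * `"converted"` -- disturbance + bloom + default-rate invasion, the
#'   full burned/plantation-like condition.
#'
#' @param scenario scenario name (above).
#' @param config a [scenario_config()].
#' @param seed integer master seed; all stage seeds derive from it.
#' @return list with `forest` and `target` (each `rna`/`dna` raw
#'   [community_table()]s), `env_forest`, `env_target`, `coords`,
#'   `scenario`, and any `newcomer_ids`/`bloomer_ids`.
#' @export
simulate_scenario <- function(scenario = c("pristine", "disturbed", "invasion",
                                           "invasion_strong", "bloom", "converted"),
                              config = scenario_config(), seed = 1) {
  scenario <- match.arg(scenario)
  coords <- nested_coords(config)
  env_f <- simulate_environment(coords, config, disturbance = 0,
                                seed = derive_seed(seed, 1))
  forest <- simulate_community(env_f, coords, config, site = "forest",
                               seed = derive_seed(seed, 2))
  traits <- forest$traits
  disturb <- scenario %in% c("disturbed", "converted")
  env_t <- if (disturb)
    simulate_environment(coords, config, disturbance = config$disturbance_mult,
                         base_env = env_f, seed = derive_seed(seed, 3))
  else env_f
  # disturbance churns the soil: the microsite patch structure is redrawn
  # without spatial coherence; otherwise the target re-samples the same
  # stand (shared presence mask), so each mechanism acts alone
  presence_t <- if (disturb && !is.na(config$disturbed_occupancy_range))
    with_seed(derive_seed(seed, 7),
              draw_presence(coords, traits, config$disturbed_occupancy_range))
  else forest$presence
  target <- simulate_community(env_t, coords, config, site = "target",
                               traits = traits, presence = presence_t,
                               seed = derive_seed(seed, 4))
  target$traits <- NULL; target$presence <- NULL
  if (scenario == "bloom" || scenario == "converted") {
    # bloom candidates: resident taxa detected in both molecules with
    # middling forest occupancy and abundance -- conversion's range
    # expanders are established but not yet dominant taxa (in converted
    # sites their occurrence typically rises from about half the samples
    # to nearly all, and their collective share severalfold)
    occ_dna <- colMeans(forest$dna$counts > 0)
    occ_rna <- colMeans(forest$rna$counts > 0)
    share_d <- colMeans(forest$dna$counts / rowSums(forest$dna$counts))
    share_r <- colMeans(forest$rna$counts / rowSums(forest$rna$counts))
    candidates <- taxon_ids(forest$dna)[
      occ_dna >= 0.35 & occ_dna <= 0.9 & occ_rna >= 0.5 &
      share_d <= quantile(share_d, 0.9) & share_r <= quantile(share_r, 0.9)]
    n_bloom <- min(config$n_bloomers, length(candidates))
    if (n_bloom < config$n_bloomers)
      warnf("only %d bloom candidates available (requested %d)",
            n_bloom, config$n_bloomers)
    target <- apply_bloom(target, candidates, n_bloom,
                          config$bloom_fold, config$bloom_homogenize,
                          seed = derive_seed(seed, 5))
  }
  if (scenario %in% c("invasion", "invasion_strong", "converted")) {
    share <- if (scenario == "invasion_strong") 0.25 else config$injection_rel_abund
    occup <- if (scenario == "invasion_strong") 1 else config$invasion_occupancy
    target <- apply_invasion(target, config$n_newcomers, share, occup,
                             seed = derive_seed(seed, 6))
    # pad forest tables with all-zero columns so both sites share one
    # taxon universe
    for (mol in c("rna", "dna")) {
      z <- matrix(0, nrow(forest[[mol]]$counts), length(target$newcomer_ids),
                  dimnames = list(rownames(forest[[mol]]$counts),
                                  target$newcomer_ids))
      forest[[mol]] <- community_table(cbind(forest[[mol]]$counts, z),
                                       forest[[mol]]$metadata)
    }
  }
  list(forest = forest[c("rna", "dna")], target = target[c("rna", "dna")],
       env_forest = env_f, env_target = env_t, coords = coords,
       scenario = scenario,
       newcomer_ids = target$newcomer_ids %||% character(),
       bloomer_ids = target$bloomer_ids %||% character(),
       bloomer_folds = target$bloomer_folds %||% numeric())
}
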