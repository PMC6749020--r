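# End-to-end orchestration: one forest/target site pair, both molecules,
# from raw tables (files or the synthetic generator) to a report bundle.

#' Pipeline run configuration
#'
#' Either a synthetic scenario (`scenario` + `generator`) or file inputs
#' (`input`: named list with, per molecule, forest/target OTU-table and
#' metadata paths, plus env TSVs).
#'
#' @param scenario synthetic scenario name for [simulate_scenario()], or
#'   `NULL` when reading files.
#' @param generator a [scenario_config()].
#' @param input optional list of file paths: `forest_rna`, `forest_dna`,
#'   `target_rna`, `target_dna` (classic OTU TSVs), `forest_metadata`,
#'   `target_metadata`, `forest_env`, `target_env`.
#' @param depth rarefaction depth (default 3790).
#' @param n_reps rarefactions averaged (default 100).
#' @param n_perm Mantel/PERMANOVA permutations (default 999).
#' @param n_perm_diffslope slope-randomization permutations (default 1000).
#' @param log10_distance regress decay on log10 distance (default TRUE).
#' @param alpha significance level (default 0.05).
#' @param seed master seed; every stage seed derives from it.
#' @param out_dir optional output directory for the JSON/TSV bundle.
#' @return a list of class `run_config`.
#' @export
run_config <- function(scenario = "converted", generator = scenario_config(),
                       input = NULL, depth = 3790, n_reps = 100,
                       n_perm = 999, n_perm_diffslope = 1000,
                       log10_distance = TRUE, alpha = 0.05, seed = 1,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

load_pipeline_input <- function(cfg) {
  if (is.null(cfg$input)) {
    sim <- simulate_scenario(cfg$scenario, cfg$generator, seed = cfg$seed)
    return(list(forest = sim$forest, target = sim$target,
                env_forest = sim$env_forest, env_target = sim$env_target))
  }
  inp <- cfg$input
  need <- c("forest_rna", "forest_dna", "target_rna", "target_dna",
            "forest_metadata", "target_metadata", "forest_env", "target_env")
  miss <- setdiff(need, names(inp))
  if (length(miss)) stopf("input lacks: %s", paste(miss, collapse = ", "))
  for (p in unlist(inp)) if (!file.exists(p)) stopf("input file not found: %s", p)
  list(forest = list(rna = read_community(inp$forest_rna, inp$forest_metadata),
                     dna = read_community(inp$forest_dna, inp$forest_metadata)),
       target = list(rna = read_community(inp$target_rna, inp$target_metadata),
                     dna = read_community(inp$target_dna, inp$target_metadata)),
       env_forest = read_env(inp$forest_env),
       env_target = read_env(inp$target_env))
}

site_analysis <- function(avg, env, cfg, stage_seed) {
  d <- canberra(avg)
  geo <- geographic(avg)
  sim <- as_similarity(d)
  env_sub <- env_table(env$values[rownames(avg$counts), , drop = FALSE])
  gow <- gower_similarity(env_sub)
  list(
    similarity = mean_pairwise_similarity(d),
    richness = richness(avg),
    decay = decay_fit(sim, geo, log10_distance = cfg$log10_distance,
                      n_perm = cfg$n_perm, seed = derive_seed(stage_seed, 1)),
    env_decay = decay_fit(gow, geo, log10_distance = cfg$log10_distance,
                          n_perm = cfg$n_perm, seed = derive_seed(stage_seed, 2)),
    mantel_comm_env = mantel_test(d, gow, n_perm = cfg$n_perm,
                                  seed = derive_seed(stage_seed, 3)),
    partial_env_given_geo = partial_mantel(d, gow, geo, n_perm = cfg$n_perm,
                                           seed = derive_seed(stage_seed, 4)),
    partial_geo_given_env = partial_mantel(d, geo, gow, n_perm = cfg$n_perm,
                                           seed = derive_seed(stage_seed, 5)))
}

#' Run the full homogenization-diagnosis pipeline
#'
#' Stages: load or simulate paired RNA/DNA tables for a forest and a
#' target (converted) site; prune collinear soil variables; rarefaction-
#' average every table; per site and molecule compute richness, Canberra
#' similarity, distance-decay (community and environment), Mantel and
#' partial Mantel tests against environment and geography; compare decay
#' slopes between sites (randomization); PERMANOVA of site on community
#' distance; classical group comparisons of similarity levels; and the
#' newcomer/bloomer mechanism report. Writes a JSON summary plus TSV
#' tables when `out_dir` is set.
#'
#' @param cfg a [run_config()].
#' @return a list report bundle (class `pipeline_result`).
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dat <- load_pipeline_input(cfg)

  env_all <- env_table(rbind(dat$env_forest$values, dat$env_target$values))
  pruned <- prune_correlated(env_all)
  keep_vars <- colnames(pruned$values)
  env_f <- env_table(dat$env_forest$values[, keep_vars, drop = FALSE])
  env_t <- env_table(dat$env_target$values[, keep_vars, drop = FALSE])

  res <- list(config = cfg, pruning_log = attr(pruned, "pruning_log"),
              retained_env_vars = keep_vars)
  for (mol in c("rna", "dna")) {
    f_avg <- rarefaction_average(dat$forest[[mol]], cfg$depth, cfg$n_reps,
                                 seed = derive_seed(cfg$seed, 31))
    t_avg <- rarefaction_average(dat$target[[mol]], cfg$depth, cfg$n_reps,
                                 seed = derive_seed(cfg$seed, 32))
    forest <- site_analysis(f_avg, env_f, cfg, derive_seed(cfg$seed, 33))
    target <- site_analysis(t_avg, env_t, cfg, derive_seed(cfg$seed, 34))
    ds <- diffslope(forest$decay$pairs, target$decay$pairs,
                    n_perm = cfg$n_perm_diffslope,
                    seed = derive_seed(cfg$seed, 35))
    # sites reuse the same grid labels; prefix them for the pooled table
    fc <- f_avg$counts; tc <- t_avg$counts
    rownames(fc) <- paste0("forest.", rownames(fc))
    rownames(tc) <- paste0("target.", rownames(tc))
    fm <- f_avg$metadata; tm <- t_avg$metadata
    rownames(fm) <- rownames(fc); rownames(tm) <- rownames(tc)
    fm$site <- "forest"; tm$site <- "target"
    both <- community_table(rbind(fc, tc), rbind(fm, tm))
    pmv <- permanova(canberra(both), both$metadata$site, n_perm = cfg$n_perm,
                     seed = derive_seed(cfg$seed, 36))
    sim_groups <- list(forest = forest$similarity$pairs,
                       target = target$similarity$pairs)
    res[[mol]] <- list(
      forest = forest, target = target,
      diffslope = ds, permanova = pmv,
      similarity_anova = anova_oneway(sim_groups),
      similarity_tukey = tukey_hsd(sim_groups),
      richness_t = t_test_two_tailed(forest$richness, target$richness))
  }
  res$rna_vs_dna_t <- list(
    forest = t_test_two_tailed(res$rna$forest$similarity$pairs,
                               res$dna$forest$similarity$pairs),
    target = t_test_two_tailed(res$rna$target$similarity$pairs,
                               res$dna$target$similarity$pairs))
  res$mechanisms <- mechanism_report(dat$forest, dat$target,
                                     depth = cfg$depth, n_reps = cfg$n_reps,
                                     n_perm = cfg$n_perm, alpha = cfg$alpha,
                                     seed = derive_seed(cfg$seed, 37))
  class(res) <- "pipeline_result"
  if (!is.null(cfg$out_dir)) write_pipeline_result(res, cfg$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result\n")
  for (mol in c("rna", "dna")) {
    r <- x[[mol]]
    cat(sprintf("[%s] similarity forest %.3f -> target %.3f | decay slope %.4g -> %.4g (diffslope p %.3g) | PERMANOVA F %.3g p %.3g\n",
                toupper(mol), r$forest$similarity$mean, r$target$similarity$mean,
                r$forest$decay$slope, r$target$decay$slope, r$diffslope$p_value,
                r$permanova$statistic, r$permanova$p_value))
  }
  print(x$mechanisms)
  invisible(x)
}

pipeline_summary_list <- function(res) {
  num <- function(p) unclass(p)[c("statistic", "p_value", "n_perm")]
  per_mol <- lapply(c("rna", "dna"), function(mol) {
    r <- res[[mol]]
    list(
      similarity = list(forest = r$forest$similarity[c("mean", "sem", "n_pairs")],
                        target = r$target$similarity[c("mean", "sem", "n_pairs")]),
      mean_richness = list(forest = mean(r$forest$richness),
                           target = mean(r$target$richness)),
      decay = list(
        forest = r$forest$decay[c("slope", "mantel_r", "mantel_p", "significant")],
        target = r$target$decay[c("slope", "mantel_r", "mantel_p", "significant")]),
      env_decay = list(
        forest = r$forest$env_decay[c("slope", "mantel_r", "mantel_p")],
        target = r$target$env_decay[c("slope", "mantel_r", "mantel_p")]),
      partial_mantel_env = list(
        forest = num(r$forest$partial_env_given_geo),
        target = num(r$target$partial_env_given_geo)),
      diffslope = num(r$diffslope),
      permanova = c(num(r$permanova), list(r2 = r$permanova$r2)),
      similarity_anova = r$similarity_anova[c("F", "df", "p_value")])
  })
  names(per_mol) <- c("rna", "dna")
  mech <- lapply(intersect(c("rna", "dna"), names(res$mechanisms)), function(mol) {
    r <- res$mechanisms[[mol]]
    list(newcomers = list(n = length(r$newcomers$taxa),
                          contributes = r$newcomers_verdict$contributes),
         bloomers = list(n = length(r$bloomers$taxa),
                         contributes = r$bloomers_verdict$contributes))
  })
  names(mech) <- intersect(c("rna", "dna"), names(res$mechanisms))
  list(seed = res$config$seed, depth = res$config$depth,
       retained_env_vars = res$retained_env_vars,
       molecules = per_mol, mechanisms = mech)
}

#' Write the pipeline report bundle
#'
#' @param res a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(pipeline_summary_list(res),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_mechanism_report(res$mechanisms, file.path(out_dir, "mechanisms.json"))
  for (mol in c("rna", "dna")) {
    da <- attr(res$mechanisms[[mol]]$bloomers, "diffabund")
    if (!is.null(da))
      write_diffabund(da, file.path(out_dir, sprintf("diffabund_%s.tsv", mol)))
    writeLines(res$mechanisms[[mol]]$newcomers$taxa,
               file.path(out_dir, sprintf("newcomers_%s.txt", mol)))
    writeLines(res$mechanisms[[mol]]$bloomers$taxa,
               file.path(out_dir, sprintf("bloomers_%s.txt", mol)))
  }
  invisible(out_dir)
}
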