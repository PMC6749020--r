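# soilhomog

Diagnosing the mechanisms of soil bacterial community homogenization after
land-use change.

When native ecosystems are converted to agriculture, soil bacterial
communities often become more similar to one another across space — *biotic
homogenization*. Two mechanisms can drive it: (1) loss of environmental
heterogeneity, which drags communities toward a common composition, and
(2) increased biotic mixing, through the arrival of taxa that were not
previously present ("newcomers") or the range expansion of resident taxa
("bloomers"). Which mechanism operates is hard to tell from a DNA survey
alone, because only a minority of soil taxa is active at any time:
16S rRNA (RNA) metabarcoding enriches for the active fraction, while the
16S rRNA gene (DNA) also captures dormant cells and relic DNA. `soilhomog`
implements the full diagnosis for spatially explicit, paired RNA/DNA OTU
surveys of a forest site and one or more converted sites.

## What it computes

Given samples×taxa count tables with coordinates, the pipeline:

- equalizes sampling effort by **averaging repeated rarefactions**
  (default 100 draws at depth 3790);
- measures community similarity as **1 − Canberra distance**
  (d(i,j) = mean over taxa with x_ik + x_jk > 0 of
  |x_ik − x_jk| / (x_ik + x_jk), so d ∈ [0,1]) and environmental
  similarity as **1 − Gower dissimilarity** over soil chemistry
  (collinear variables pruned at R² > 0.6, p < 0.05);
- quantifies spatial turnover by the **distance-decay** regression of
  pairwise similarity on log10 geographic distance, with significance by
  the **Mantel** permutation test, contributions of environment vs.
  geography by the **partial Mantel** test, slope changes between sites by
  a **randomization test on the slope difference**, and overall
  composition differences by **PERMANOVA** (pseudo-F on Canberra
  distances);
- identifies **bloomers** with a negative-binomial Wald test (log link,
  median-of-ratios size-factor offsets, Cox–Reid dispersion estimation
  moderated toward a mean–dispersion trend; positive log2 fold change at
  BH-adjusted p < 0.05) and **newcomers** as taxa detected in a converted
  site but in no forest sample;
- runs the **removal-and-recompute** analysis: drop a candidate taxon set,
  re-rarefy, and ask whether mean pairwise similarity falls back to forest
  levels — the operational test of whether that set *causes* the
  homogenization.

A spatially explicit generator of paired RNA/DNA communities
(`simulate_scenario()`) provides ground-truth scenarios — pristine,
disturbed, invasion, bloom, converted — against which every stage is
validated.

## Worked example

```r
library(soilhomog)

cfg <- scenario_config(n_taxa = 400, depth_range = c(2000, 4000),
                       rarefaction_depth = 1000, rarefaction_reps = 20,
                       n_newcomers = 60, n_bloomers = 40)
sim <- simulate_scenario("converted", cfg, seed = 42)

forest_rna <- rarefaction_average(sim$forest$rna, depth = 1000,
                                  n_reps = 20, seed = 1)
d <- canberra(forest_rna)
decay_fit(as_similarity(d), geographic(forest_rna), n_perm = 999, seed = 2)
#> distance-decay: slope = -0.09856 per decade of distance,
#>                 Mantel r = 0.819, p = 0.001

gow <- gower_similarity(env_table(sim$env_forest$values))
partial_mantel(d, gow, geographic(forest_rna), n_perm = 999, seed = 3)
#> permutation test: statistic = 0.5474, p = 0.001 (999 permutations)

mechanism_report(sim$forest, sim$target, depth = 1000, n_reps = 20,
                 n_perm = 199, seed = 7)
#> mechanism report
#> [RNA] forest similarity 0.331 +/- 0.013
#>   newcomers (62 taxa): similarity 0.367 -> 0.404 | contribute: no
#>   bloomers (26 taxa): similarity 0.367 -> 0.298 | contribute: yes
#> [DNA] forest similarity 0.353 +/- 0.004
#>   newcomers (64 taxa): similarity 0.345 -> 0.367 | contribute: no
#>   bloomers (28 taxa): similarity 0.345 -> 0.303 | contribute: yes
```

Read it as follows. The undisturbed forest shows spatial structure: RNA
community similarity falls by ~0.1 per decade of distance (Mantel
p = 0.001), and environmental similarity predicts community similarity
even after controlling geography (partial r = 0.55). In the converted
site, removing the *newcomer* taxa **raises** similarity (0.367 → 0.404) —
newcomers add variation and cannot explain homogenization — while removing
the *bloomer* taxa drops similarity to forest levels (0.367 → 0.298 vs.
forest 0.331): the range expansion of resident taxa is what homogenized
the community. `run_pipeline(run_config(...))` wraps the whole sequence,
including PERMANOVA, richness, ANOVA/Tukey group comparisons, slope
randomization, and a JSON/TSV report bundle.

Real data enter through `read_community()` (classic `#OTU ID` TSV or
BIOM + metadata TSV with `sample_id, site, molecule, x, y`) and
`read_env()` (soil chemistry TSV).

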