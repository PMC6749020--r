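---
title: "Diagnosing soil community homogenization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing soil community homogenization: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the statistical
model behind each stage, the parameters that matter and why their defaults
are what they are, what the synthetic-community generator does and does
not emulate, and the design decisions taken where more than one defensible
choice existed.

## The diagnostic question

Converted (burned, planted) soils often host bacterial communities that
are more similar to each other across space than forest soils are —
biotic homogenization. The package quantifies that pattern and attributes
it to one of two mechanism families:

* **environmental convergence** — the soil environment loses spatial
  structure and communities, tracking it, lose theirs;
* **biotic mixing** — either taxa absent from the forest arrive
  (*newcomers*), or resident taxa expand in abundance and occupancy
  (*bloomers*).

The paired RNA/DNA design matters because 16S rRNA enriches for the
active fraction of the community, which is the fraction expected to track
environmental change, while the 16S rRNA gene pool also carries dormant
cells and relic DNA.

## Pipeline stages and their assumptions

**Rarefaction averaging.** Raw counts are subsampled without replacement
to a common depth (default 3790) and averaged over `n_reps` independent
draws (default 100). Averaging removes most of the subsampling noise of a
single rarefaction; every averaged row still sums to the depth (each
entry's expectation is the hypergeometric mean `depth * count/rowsum`,
which the test suite verifies at 1000 replicates). Samples below the
depth are dropped with a warning rather than an error, because real
surveys routinely lose a few under-sequenced samples. A taxon counts as
*detected* in an averaged table when its averaged count is positive,
i.e., it was drawn in at least one rarefaction — the most inclusive rule;
`identify_newcomers(min_reps =)` exposes a stricter one (present in at
least k of the rarefactions).

**Community dissimilarity.** Canberra distance in its *averaged* dialect:
the mean over non-double-zero taxa of `|x-y|/(x+y)`. This form is bounded
in [0,1], so `1 - d` is a meaningful similarity, and it weights rare taxa
equally with dominant ones — which is precisely why dominance shifts
(blooms) move it: amplified taxa become spatially even (their terms
shrink), and squeezed rare taxa drop into excluded double zeros. The
unaveraged textbook sum is available behind `canberra(average = FALSE)`.
Note one consequence used throughout: the per-taxon Canberra term is
invariant to multiplying a taxon by a constant across all samples, so
*pure* proportional amplification does not change the distance — occupancy
and evenness changes do.

**Environmental similarity.** Gower dissimilarity (range-normalized
Manhattan for numeric variables, simple matching for factors, via
`cluster::daisy`), returned as `1 - d`. Zero-range variables carry no
information and are dropped with a warning. Before any similarity is
computed, collinear chemistry variables are pruned greedily: while any
pair has Pearson R² > 0.6 at p < 0.05, the member of the worst pair with
the larger mean |r| to all other variables is removed (the tie-break had
to be chosen; larger mean |r| removes the most redundant variable first).

**Distance-decay.** OLS of pairwise similarity on log10 distance.
The log scale is the package default because nested sampling designs span
three orders of magnitude of distance (0.1–141 m here) while similarity
stays within a narrow band; a linear axis is available
(`log10_distance = FALSE`). Significance of the association is a Mantel
test, not the OLS t-test, because pairs sharing a sample are not
independent. Following the field's plotting convention, a decay fit is
flagged `significant` (trend line drawn) only when the Mantel p < 0.05.

**Permutation inference.** Mantel and partial Mantel correlate
off-diagonal dissimilarities (similarity-tagged inputs are converted
internally, so the sign of r is always interpretable); the null permutes
rows and columns of the first matrix simultaneously; the partial variant
permutes the raw first matrix, the simplest standard choice. The default
tail is one-sided in the direction of the observed statistic. The
slope-difference randomization (`diffslope`) reshuffles pair-set
membership between the two datasets, refitting both slopes each
permutation; its default tail is two-sided on |difference| because the
direction of a slope change is usually not specified in advance (a
one-sided option exists). PERMANOVA partitions the total sum of squared
distances into among- and within-group parts and permutes group labels.
All p-values use the `(extreme + 1)/(n_perm + 1)` correction and are
reproducible given a seed; the test suite checks each test against
exhaustive enumeration on 4–5-sample fixtures and verifies type-I error
within [0.03, 0.07] at nominal 0.05 over 1000 null simulations.
Permutation counts default to 999 (Mantel family, PERMANOVA) and 1000
(diffslope). Correlation is Pearson by default, Spearman by option.

**Group comparisons.** Mean within-group pairwise similarity ± SEM over
the n(n−1)/2 pairs, compared across sites by one-way ANOVA with Tukey HSD
post hoc, and across molecules by the pooled-variance two-tailed t-test.
Pairwise similarities are pseudoreplicated (each sample enters n−1
pairs), so these classical tests are reproduced as the field uses them,
but `similarity_gap_permtest()` offers a sample-level permutation
alternative as a robustness line, and all pair counts and degrees of
freedom are reported rather than assumed.

**Differential abundance.** A compact negative-binomial Wald test on raw
integer counts: median-of-ratios size factors (positive-count fallback
when no taxon is ubiquitous), per-taxon Cox–Reid-adjusted profile
likelihood for the dispersion maximized on a zoomed log-alpha grid
(36-point coarse pass over 1e-8–100, two 12-point refinements), a lowess
log-log mean–dispersion trend recalibrated by the trimmed mean ratio, and
a maximum-a-posteriori dispersion that maximizes the penalized likelihood
with a log-normal prior centered on the trend. The prior width is set
adaptively: the robust spread (mad²) of log-dispersion residuals around
the trend minus the estimates' sampling variance (`trigamma((n-2)/2)`),
floored at 0.25². MAP estimation rather than a weighted average of logs
matters in one specific regime: taxa whose counts happen to look
underdispersed have a flat likelihood as dispersion approaches zero, and
an averaging rule would leave them with near-Poisson standard errors and
inflated false positives, while the prior correctly dominates there. The
Wald statistic uses a t reference with n−2 degrees of freedom — the usual
small-sample correction when the dispersion is estimated. There is no
fold-change shrinkage and no outlier refitting: the target of inference
is the *set* of enriched taxa, and the suite validates exactly that
(type-I within [0.03, 0.07]; ≥80% power at a true log2 fold change of 2
with 13 vs 13 samples; mean estimated LFC within ±0.3; near-identity of
fold changes with DESeq2 on well-covered taxa, Pearson r > 0.99).
Coefficients are clamped (|log-scale group effect| ≤ 15) so taxa absent
from one group report a large finite fold change rather than diverging.
"Low-abundance sample" exclusion is a configurable minimum-depth filter
(`min_sample_depth`), applied to samples, with a separate optional
mean-count filter for taxa (`min_base_mean`, off by default).

**Mechanism attribution.** Newcomers: detected in the converted site,
in no forest sample. Bloomers: positive log2 fold change at BH-adjusted
p < 0.05 *and* detected in the forest — bloomers are range expansions of
resident taxa, and the reference-presence restriction (configurable off)
keeps the newcomer and bloomer sets disjoint so the two mechanisms are
separately attributable. The removal analysis drops the candidate set,
re-rarefies at the same depth (lowering it with a warning if removal
starves a sample), and recomputes similarity and decay. The verdict rule
is made explicit, since the verbal argument it formalizes admits
ambiguity: a set **contributes** to homogenization iff its removal
significantly lowers mean similarity (Tukey, removed vs. all-taxa,
α = 0.05) *and* the post-removal similarity is not significantly above
the forest level (Tukey, removed vs. forest). Both the raw direction and
the test results are reported, so a reader can apply a different rule.

## The synthetic-community generator

The generator produces paired RNA/DNA integer count tables for a forest
site and a converted-site counterpart with the statistical structure the
analysis assumes, so that every stage can be validated against ground
truth without any external data.

**Sampling design.** 13 points per site: the four corners of a 100 m
quadrat plus the three non-shared corners of 10, 1, and 0.1 m quadrats
nested at one corner. Pairwise distances span 0.1 to 141.4 m.

**Environment.** Each of 7 soil variables is a Gaussian random field over
the sample points with exponential covariance `exp(-d/50 m)` plus a 0.05
nugget. The first variable is the niche axis; two of the others are
strongly collinear with it (ρ = 0.9, 0.85 — these exercise the variable
pruning), the rest progressively less so. Disturbance adds per-sample
noise that is mostly a *shared shock* across variables (sd = 4 field
units, plus 40% variable-specific noise): burn intensity is patchy in
space but moves organic matter, pH, and nutrients jointly. This destroys
the spatial structure of the environment and inflates its variance while
keeping the chemistry internally correlated — which is what lets the
active community keep tracking measured chemistry after conversion.

**Communities.** Taxon expected relative abundance ∝ log-normal base
abundance (σ = 1.5) × Gaussian niche kernel on the standardized niche
axis (width 1.5 ± 50%) × a microsite presence mask. The mask is the
patchiness model: each taxon occupies a Beta(2,1)-distributed fraction of
samples, with presences spatially aggregated only at the sub-meter scale
(patch range 1 m), so patchiness behaves as noise at the plot scale and
the plot-scale distance-decay flows through the environmental channel.
The RNA layer draws from the active taxa (60%) with the niche kernel
raised to a coupling power (1.5): active taxa track the environment more
tightly. The DNA layer is a mixture of that same composition (65%) and a
relic/inactive pool (35%) that is blind to the niche axis and only weakly
spatially coupled — a shared heavy-tailed composition with per-sample
log-normal noise (sd 1). Counts are multinomial at per-sample depths
drawn uniformly from 5000–20000 (2000–4000 at the reduced test scale).
Baseline parameters (niche width, coupling, relic fraction) were fixed
once so the forest scenario reproduces the qualitative baselines the
analysis presumes — significant community distance-decay in both
molecules, significant environmental decay, community–environment partial
Mantel structure, and a mean pairwise similarity in the 0.27–0.36 band
typical of Canberra similarities on soil 16S data — and were not revisited
afterwards.

**Conversion mechanisms.** Scenarios isolate one mechanism at a time; the
non-disturbance scenarios reuse the forest's environmental field and
presence mask (the target is a re-sampling of the same stand), so the
injected mechanism is the only systematic difference:

* `invasion`: novel taxon columns, absent from the forest by
  construction, occupying 25% of samples (newly arrived taxa are
  geographically narrow) at a collective 2% community share — the
  few-percent share and quarter-occupancy of typical field newcomers.
  `invasion_strong` (share 0.25, full occupancy) is the regime in which
  invasion *should* be mechanistically attributable, and is what the
  attribution validation uses.
* `bloom`: 50 resident taxa — drawn from mid-occupancy, mid-abundance
  taxa detected in both molecules — amplified by per-taxon log-normal
  folds (median 4, log-sd 0.6) while their expected spatial profile is
  pulled 75% toward a uniform one. The flattening is the substantive
  modeling choice: because the per-taxon Canberra term is
  scale-invariant, a bloom homogenizes through occupancy and evenness,
  not through multiplication alone; a blooming taxon grows wherever
  resources appear, decoupling from its old microsite pattern. The
  default reproduces the field signature of bloomers: occurrence
  frequency rising from about half the samples to most of them, and a
  severalfold rise of collective share.
* `disturbed`: the environmental shock only.
* `converted`: disturbance + bloom + default-rate invasion, the full
  burned/plantation-like condition.
* `pristine`: an independent count draw from the same expectations — the
  null scenario.

**What the generator does not emulate.** Phylogenetic structure, temporal
dynamics, read-level error, taxon interactions, and dispersal kernels are
absent; patchiness is stationary; the relic pool is compositionally
static. One known quantitative limitation: in the `converted` scenario
the DNA layer's mean similarity does not reliably rise above the forest's
— the environmental-channel cost of conversion outweighs the DNA share of
the bloom gain — whereas RNA similarity rises consistently. The
paper-direction validation therefore evaluates the similarity-rise
contrast on the RNA layer, where the homogenization signal is strongest;
all DNA-layer contrasts that the suite does assert (decay loss, weaker
environmental coupling than RNA, bloomer attribution, newcomer
non-contribution) reproduce. Passing tests on this generator show the
pipeline recovers mechanisms *under these assumptions*; they cannot show
robustness to, e.g., phylogenetically clustered invasions or
depth-confounded designs.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit seed; the pipeline derives
  per-stage seeds from one master seed by fixed offsets
  (`derive_seed`), and `with_seed()` restores the caller's RNG state, so
  package calls never perturb the global stream. Fixed seed implies
  byte-identical output.
* Rarefaction uses exact without-replacement subsampling
  (`sample()` on the expanded count vector), not a multinomial
  approximation.
* The dispersion grid spans 1e-8–100 with two zoom rounds (resolution
  ~1.5% in log-alpha at the end); dispersions are floored at 1e-8; IRLS
  runs to a 1e-8 coefficient tolerance with a 50-iteration cap.
* Degenerate inputs fail loudly and early: non-integer counts reaching
  rarefaction or the NB test, samples missing from metadata (named in the
  error), all-zero expected compositions, distance matrices with
  mismatched labels, zero distances under a log transform, empty sample
  pairs under Canberra.
* Where the design was genuinely open we chose: one rarefaction depth
  across strata (configurable, rather than per-stratum depths); Pearson
  correlation in the Mantel family (Spearman by option); the two-sided
  default for `diffslope`; all-numeric treatment of chemistry variables;
  sample-level (not taxon-level) interpretation of the low-abundance
  exclusion, with a separate taxon filter.

## Validation problem sizes

The test suite and the acceptance script exercise the same model at a
reduced size chosen to keep a full validation run in minutes on one CPU:
400-taxon pools, depths 2000–4000, rarefaction depth 1000 averaged over
20 draws, 60 newcomers / 40 bloomers, with effect sizes (fold, shares,
coupling, relic fraction, disturbance) at the defaults above. At this
size the suite runs exhaustive-enumeration oracles for every permutation
test, 1000-replicate null calibrations, 50-replicate mechanism
attribution per scenario, and the RNA/DNA qualitative contrasts. The
full-size defaults (2000 taxa, depths 5000–20000, depth 3790 × 100
rarefactions) run the same code paths in minutes per pipeline call.
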