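---
title: "Methods: detecting host-population signal in gut metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting host-population signal in gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codivkit)
```

# Scope and model of the data

`codivkit` analyses multi-population gut-metagenome surveys after the
upstream bioinformatics is done. Its inputs are (a) a samples × features
table of read counts against a catalogue of MAG species (or taxa), with
genome lengths and per-sample genome coverage fractions; (b) a gene-level
CAZyme annotation table (CAZy family, EC number, counts per sample); and
(c) strain- or gene-level trees whose tips are samples. The scientific
question throughout is whether the *host population* (e.g. Hadza,
non-indigenous adults and children, and two chimpanzee communities — or the
coarser *Homo* vs *Pan* split) structures the microbial data: in
composition, in encoded carbohydrate-degrading function, and in strain
phylogeny (phylosymbiosis).

Read mapping, assembly, binning, tree inference and functional prediction
are out of scope; trees and annotation tables are consumed, not built.

# Abundance construction

Counts are first cleaned by a **coverage-ratio filter**: a genome counted in
a sample whose observed covered fraction is far below the coverage its read
count should produce is almost certainly cross-mapping noise. We zero cells
with observed/expected covered fraction < 0.5 (`coverage_filter()`,
threshold configurable, `>=` keeps the boundary). The ratio direction —
observed over expected — is our reading of the filter's intent (removing
*under*-covered genomes); the threshold applies to that quotient.

Samples are then **rarefied** (`rarefy()`) by a single uniform subsample
without replacement to the minimum sample total (or a user depth); samples
below the depth are dropped, never padded, and the drop is reported. One
draw is used rather than a repeated-rarefaction mean because downstream
statistics expect one integer table. Finally **TPM** (`tpm_transform()`)
divides each count by its genome length in kb and rescales each sample to
10⁶, making abundances comparable across genomes of different size; this
length adjustment is also what the ordination consumes, so its PCA operates
on genome-size-adjusted data.

# Compositional statistics

Relative abundance data are compositional, so comparisons are made in
log-ratio coordinates. `clr_transform()` maps each sample to
$\mathrm{clr}(x)_i = \ln x_i - \frac{1}{D}\sum_j \ln x_j$; rows sum to zero
and the transform is invariant to per-sample scaling. Zeros must be replaced
first:

* `replace_zeros_bayesian()` — Bayesian-multiplicative replacement with a
  Jeffreys-like per-feature prior strength of 0.5 (configurable): each zero
  in a row with total $t$ becomes $t\,s/(t + sD)$ and non-zero entries are
  shrunk so the row total is preserved. Used before ordination.
* `replace_zeros_pseudocount()` — a fixed pseudocount, default $10^{-6}$,
  used by the CAZyme bootstrap where a hard detection floor on fractions is
  the intended behaviour.

Richness is the count of detected features, Shannon diversity is computed in
nats via vegan. Population differences in these per-sample scalars are
tested with pairwise two-sided Wilcoxon rank-sum tests (exact when sample
sizes permit), and distributional differences (e.g. phylum profiles) with
pairwise two-sample Kolmogorov–Smirnov tests; both are Benjamini–Hochberg
corrected across the population pairs.

The **core microbiome** rule is deliberately explicit because "core" has no
single field definition: a feature is core to a population when detected
above `min_abundance` (default 0) in at least a `prevalence` fraction
(default 1.0, i.e. every sample) of that population; the cross-population
core is the intersection. Both knobs are parameters, so looser conventions
(e.g. 50% prevalence) are one argument away.

# Differential abundance: Monte-Carlo Dirichlet effect sizes

Count tables carry sampling noise that plug-in CLR ignores. Following the
ALDEx family of methods, `dirichlet_clr_instances()` draws, per sample,
`n_mc = 128` Dirichlet realizations with prior 0.5 added to every cell and
CLR-transforms each (the Dirichlet normalization cancels inside the CLR, so
instances are computed directly from Gamma draws). `effect_size()` then
summarizes, per feature:

* `diff_btw` — the median, over instances and random cross-group sample
  pairings, of the signed CLR difference (group 2 minus group 1);
* `diff_win` — the median over instances of the **larger** of the two
  within-group median absolute differences between randomly paired samples;
* `effect = diff_btw / diff_win`, with |effect| ≥ 1 the call threshold.

The literature states the denominator both as the largest *within*-group and
the largest *between*-group difference; we use `max(diff.win)`, the
dispersion-style denominator consistent with the reference implementation of
the method, so the effect reads as "how many typical within-group spreads
separate the groups". If the within-group spread is exactly zero the effect
is 0 when `diff_btw` is 0 and otherwise a capped sentinel (±20 by default).
Random pairings are drawn per group level in sorted-level order, which makes
the statistic *exactly* antisymmetric under swapping the contrast. Welch's
t-test and a Wilcoxon test on instance-averaged CLR values accompany the
effect, each BH-corrected; note that under strong compositional closure
p-values can be small for features whose effect is still < 1 — the effect
threshold, not the p-value, is the call criterion.

# Ordination

`pca_svd()` performs PCA by SVD of the column-centred (and by default
unit-scaled) CLR matrix; explained variance per component is
$\sigma_k^2/\sum\sigma^2$, and signs are fixed so the largest-magnitude
loading of each component is positive. Rank-1 inputs are allowed (PC1
explains everything); a rank-0 (constant) matrix is an error. Before the
PCA, `filter_features()` reduces dimensionality: features below the median
on *both* CLR variance and mean CLR abundance are dropped, then the table is
trimmed by decreasing variance to at most 100 features (and never more
features than samples). The two-criteria-then-variance order is our
resolution of the loosely specified "low variance or low mean" rule; both
the cap and the rule's parameters are arguments.

`density_contours()` summarizes the score cloud per population with a
Gaussian KDE (Scott-type bandwidth per population, shared grid) and masks
cells below a fraction — 10% by default, 50% for sparser data — of that
population's peak density; samples falling in masked cells are returned
individually, matching the convention of drawing contour-excluded samples
as points.

# Phylosymbiosis: PERMANOVA on patristic distances

`patristic_distances()` (via ape) gives tip-to-tip path lengths;
`permanova()` is implemented from scratch on squared distances:

$$SS_{total} = \tfrac1n \sum_{i<j} d_{ij}^2,\qquad
  SS_{within} = \sum_g \tfrac1{n_g} \sum_{i<j \in g} d_{ij}^2,$$

$R^2 = SS_{between}/SS_{total}$ and pseudo-F with $(k-1, n-k)$ degrees of
freedom. Distances are used raw (no square-root or standardization). The
p-value shuffles labels 999 times by default; when the number of distinct
label arrangements is ≤ 10,000 all arrangements are enumerated and the
p-value is exact. Under random labels $E[R^2] = (k-1)/(n-1)$ exactly, a
property the tests verify by enumeration.

`gene_screen()` applies this per gene tree, BH-adjusts p across trees, and
flags R² > 0.5 as strong host-gene specificity. A tree is *amenable* when it
has ≥ 4 tips and ≥ 2 populations with ≥ 2 tips each — our operationalization
of an unstated inclusion criterion; skipped trees are reported with reasons,
never silently dropped. When a sample contributes several tips to one tree
we keep the copy with the smallest mean distance to all tips (most central),
with `multi_copy = "keep_all"` as the alternative.

# CAZyme substrate shifts

`assign_substrates()` joins genes to a substrate map on (family, EC) with a
family-level fallback (blank-EC rows); unmapped genes are audited and kept
in total-gene denominators so fractions are honest.
`population_relative_abundance()` divides each substrate's gene count by the
population's *total* CAZyme gene count. `bootstrap_group_difference()` tests
group shifts: per-sample substrate fractions, zeros → $10^{-6}$, CLR across
substrates within each sample, observed statistic = difference of group mean
CLR per substrate, and 10,000 stratified bootstrap replicates (samples
resampled with replacement within each group, sizes preserved); the 95%
percentile CI must exclude zero for significance. The CLR axis is ambiguous
in the method's verbal description ("geometric mean ... for that substrate
across hosts"); we default to the within-sample axis, the compositionally
coherent reading, and provide `clr_axis = "substrate"` for the per-substrate
across-hosts variant. The bundled `default_substrate_map()` is **synthetic**
— 50 plausible substrate groups across plant, host and microbial glycan
sources — intended for simulation and testing; real analyses supply a
curated map.

# The synthetic generator and what it does (not) emulate

`generate_count_table()` draws Dirichlet-multinomial counts around
population baselines: log-normal (σ = 1) baseline proportions sorted in
decreasing abundance (so planted feature indices are interpretable),
concentration 50 — overdispersion θ ≈ 0.02, typical of stool surveys —
Poisson depths around 10⁵ reads, log-normal genome lengths around 2.5 Mb,
and Lander–Waterman coverage (expected fraction $1 - e^{-\lambda}$, observed
= expected × Beta(20, 1) noise). Planted fold-changes multiply one
population's baseline proportion by $2^{LFC}$ before renormalization, and
the full per-population proportion table is emitted as ground truth.
`generate_cazyme_table()` distributes a fixed 2,000 genes per sample
multinomially over the map's family-EC rows, multiplying shifted substrates'
weights in the target host group. `generate_population_trees()` grafts
within-population coalescent subtrees onto a pure-birth population backbone;
the signal dial scales the backbone depth by strength (star-like at 0) and
within-population branches by (1 − strength), and shuffles each tip into a
random pool with probability (1 − strength) — one dial from exchangeable
null to perfect population monophyly.

These generators emulate overdispersed, long-tailed count data with
controllable effect sizes; they do **not** emulate real-data features such
as sample-specific contamination, batch effects, phylogenetically correlated
abundances, unequal group depths, or annotation error. Passing recovery
tests therefore demonstrates that the statistics recover signal *of the
planted form at realistic noise levels*, not that any particular biological
dataset will behave as cleanly.

# Numerical and design choices

* Rarefaction and every Monte-Carlo stage take explicit seeds; the pipeline
  derives stage seeds from one master seed and re-runs byte-identically.
* CLR errors name the first offending non-positive cell rather than failing
  inside `log()`.
* PERMANOVA compares permuted F against observed F with a 10⁻¹² slack so
  exact ties (e.g. fully degenerate distances) count as ≥.
* The effect-size sentinel (±20) marks infinite effects without poisoning
  downstream sorting; BH is applied via `p.adjust`.
* Validation problem sizes (50 tree seeds, 20 bootstrap/effect seeds,
  500-feature null tables, 10,000 bootstrap replicates, 128 Monte-Carlo
  instances) were chosen so the whole suite exercises every claim at
  desk scale; the same quantities are recomputed by
  `scripts/acceptance.R`.

# Known limitations

* The PERMANOVA handles a single grouping factor (one-way design); no
  covariates or nested terms.
* Differential abundance supports exactly two groups; multi-group contrasts
  are run pairwise.
* The bootstrap CI is percentile-based; no BCa correction, so very small
  groups (< ~5 samples) can be anti-conservative.
* The core-microbiome rule, coverage-ratio direction, ordination feature
  rule and bootstrap CLR axis are all points where field practice is
  under-specified; each is an explicit, documented parameter rather than a
  hidden constant, and changing them changes results.
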