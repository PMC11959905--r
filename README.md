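# codivkit

Statistics for detecting **host-population signal in gut metagenomes** —
whether the microbiomes (and microbial strains) of different host
populations, such as human and chimpanzee communities sampled in the same
region, diverge in composition, function and phylogeny.

The package implements the downstream statistical layer of a
MAG-based (metagenome-assembled genome) comparative survey:

* **Abundance construction** — rarefaction to even depth, genome
  coverage-ratio filtering (observed/expected covered fraction ≥ 0.5), and
  TPM (transcripts-per-kilobase-million) normalization.
* **Compositional statistics** — CLR transform
  `clr(x)_i = ln x_i − (1/D) Σ_j ln x_j` with Bayesian-multiplicative or
  pseudocount zero replacement, richness and Shannon diversity, pairwise
  Wilcoxon/Kolmogorov–Smirnov tests with Benjamini–Hochberg FDR, and a
  configurable core-microbiome prevalence rule.
* **Differential abundance** — an ALDEx-style Monte-Carlo Dirichlet scheme:
  per-sample Dirichlet(counts + 0.5) CLR instances, Welch's t and Wilcoxon
  tests, and the effect size
  `effect = diff.btw / max(diff.win)` (median between-group CLR difference
  over the larger within-group median absolute difference), with |effect| ≥ 1
  as the call threshold.
* **Ordination** — CLR-PCA by SVD with variance/mean feature reduction
  (≤ 100 features), and per-population kernel-density contours truncated at a
  fraction (default 10%) of each population's peak.
* **Phylosymbiosis** — patristic distances of strain/gene trees and a
  from-scratch PERMANOVA
  (`R² = SS_between / SS_total`, pseudo-F, permutation or exact p), plus a
  gene-tree screen flagging trees with R² > 0.5 as host-specific.
* **CAZyme substrate shifts** — (family, EC) → glycan substrate → source
  category (plant / host / microbial glycans) annotation, population
  relative abundances, and a 10,000-replicate bootstrap on CLR-transformed
  per-sample substrate fractions: a shift is significant when the 95% CI of
  the group difference excludes zero.
* **Synthetic data with planted truth** — Dirichlet-multinomial count tables
  with planted log2 fold-changes, CAZyme tables with planted substrate
  enrichments, and trees with a tunable within-population clustering dial,
  so every stage is validated by recovering known signal.

## Worked example

Simulate a two-population survey (20 samples each, 200 MAGs) with one MAG
planted at log2 fold-change 4 in the second population, a 4× pectin-degrading
enrichment in the chimpanzee group, and strong tree signal:

```r
library(codivkit)

cfg <- synth_config(seed = 11)
sig <- planted_signal(
  differential_features = data.frame(feature = 10, population = 2, lfc = 4),
  substrate_shifts = data.frame(substrate = "pectin", host_group = "Pan",
                                enrichment = 4),
  tree_signal_strength = 0.9)

sim  <- generate_count_table(cfg, sig)
rare <- rarefy(coverage_filter(sim$counts), seed = 1)
da   <- diff_abundance(rare, sim$design, seed = 2)
head(call_significant(da), 3)
#>    feature diff_btw diff_win   effect      welch_p      welch_q   wilcoxon_p
#> 10   F0010 3.335062 1.057737 3.153017 1.931867e-10 3.863734e-08 1.450889e-11
#>      wilcoxon_q significant
#> 10 2.901778e-09        TRUE
```

The planted MAG is the only feature with |effect| ≥ 1: its between-group CLR
shift (3.34, close to ln 2⁴ ≈ 2.77 plus compositional closure) is three
times the within-group spread. The strain tree carries the planted
host-population structure:

```r
ts <- generate_population_trees(cfg, sig, n_trees = 1)
permanova(patristic_distances(ts$trees[[1]]),
          setNames(ts$design$population, ts$design$sample))
#> PERMANOVA: R2 = 0.6378, pseudo-F = 66.907, p = 0.001 (999 permutations)
#>   n = 40 tips; 2 groups ( Pop1:20, Pop2:20 )
```

64% of the patristic variation is explained by host population. And the
planted pectin enrichment is picked up by the bootstrap CI:

```r
caz <- generate_cazyme_table(cfg, sig)
fr  <- sample_substrate_fractions(assign_substrates(caz$genes))
bt  <- bootstrap_group_difference(fr, caz$design, seed = 3)
bt[bt$substrate == "pectin", ]
#>        substrate estimate ci_lower ci_upper n_replicates significant
#> pectin    pectin 1.350815 1.265077 1.437089        10000        TRUE
```

The CLR difference estimate 1.35 ≈ ln 4 − closure, with a 95% CI well away
from zero. `run_pipeline(run_config(out_dir = "out"))` chains all stages and
writes one tidy TSV per stage plus a JSON manifest.

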