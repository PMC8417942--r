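# topostrat

Topological stratification of population-scale gut-microbiome cohorts.

## What problem this solves

Population microbiome surveys pool genus-level abundance tables from many
studies and countries. Conventional ordination compresses these highly
non-linear data to a couple of axes before testing group differences;
`topostrat` instead summarises the full Bray–Curtis geometry as a Mapper
network — project samples through a 2-D metric-MDS lens, cover the lens
with an overlapping grid, density-cluster each rectangle in the original
distance space, and link clusters that share samples — and then asks which
host variables and taxa *structure* that network. It is aimed at
microbiome researchers who want stratification and association analysis
(which countries, metadata levels and genera occupy and share regions of
composition space) rather than single-taxon differential abundance.

## The statistics at its core

* **Bray–Curtis dissimilarity**
  `BC(x, y) = 1 − 2·Σ min(x_i, y_i) / (Σ x_i + Σ y_i)` on total-sum-scaled
  samples; 2-component metric MDS (SMACOF) of the precomputed matrix as
  the Mapper lens; DBSCAN inside each cover rectangle with `eps` at the
  0.95 nearest-rank quantile of nearest-neighbour distances.
* **H0 persistence**: single-linkage merge heights as a birth–death
  diagram; the largest gap between consecutive deaths counts the robust
  clusters, a sanity check for the network's component count.
* **SAFE** (spatial analysis of functional enrichment): per node `v`, the
  attribute sum over its hop-distance neighbourhood is compared with `P`
  permutations of the attribute across nodes;
  `p_v = (1 + #{perm ≥ obs}) / (1 + P)` and
  `S_v = log10(p_v) / log10(1/(1+P)) ∈ [0, 1]`. The sum of `S_v` over
  significantly enriched nodes (`p < 0.05`) is the network-level **SAFE
  enriched score** used to rank variables.
* **Co-enrichment**: one-sided Fisher exact (hypergeometric tail) test on
  the overlap of two variables' enriched node sets, binarized at the 0.5th
  nearest-rank percentile of all pairwise p-values; per node, the
  most-enriched variable stratifies the network.

A fully seeded synthetic-cohort generator (unbalanced country groups,
study-specific taxon panels with structural zeros, overdispersed Dirichlet
compositions, planted country–taxon effects) makes every stage testable
without downloading anything.

## Worked example

Two countries of 50 samples, 30 genera, one planted ×5 concentration
effect (Brazil, `g5`):

```r
library(topostrat)

cp <- default_country_params()[1:2, ]
cp$n <- c(50L, 50L)
spec <- synthetic_spec(cp, n_taxa = 30L, n_studies = 3L, panel_fraction = 1,
                       base_concentration = rep(1, 30),
                       planted_effects = data.frame(country = "Brazil",
                                                    taxon = "g5", effect = 5),
                       seed = 101L)
cfg <- pipeline_config(synthetic = spec, out_dir = "run1",
                       resolution = 8L, overlap = 0.85, min_samples = 3L,
                       n_permutations = 999L, variables = "country")
res <- run_pipeline(cfg)
res$network
#> Mapper network: 38 nodes, 96 edges, 71 retained samples
head(res$ranking, 6)
#>         variable safe_enriched_score n_enriched
#> 1 country=Brazil           10.257077         12
#> 2 country=Canada            9.602862         13
#> 3            g26            9.292083         12
#> 4            g11            8.592327         11
#> 5            g29            8.035968          9
#> 6             g4            7.933415          9
res$coenrichment
#> co-enrichment over 33 variables: 3 significant pair(s) at threshold 1.35e-06
res$coenrichment$binary_matrix["country=Brazil", "g5"]
#> [1] 1
```

Reading this: 71 of 100 samples survive clustering (cover ratio 0.71);
the planted country tops the SAFE ranking, its enriched score (10.26, from
12 significant nodes) acting as a network-level effect size; and the
planted (Brazil, g5) pair is among the 3 pairs surviving the strict
co-enrichment binarization. `run1/` holds the cohort summary, H0 diagram,
GraphML network + membership JSON, SAFE tables, co-enrichment matrices,
stratification table and a manifest that reproduces the run byte for
byte.

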