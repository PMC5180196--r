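# metacomm

Metacommunity assembly inference for microbial community surveys.

`metacomm` asks, for a set of bacterioplankton (or other microbial) samples
collected over space and time: **which metacommunity paradigm explains the
observed variation in community composition?** Local environmental control
(species sorting, SS), dispersal from source populations overriding local
sorting (mass effect, ME), or spatial/stochastic structure (neutral model /
patch dynamics, NM/PD)? It also quantifies phylogenetic relatedness within
samples (habitat filtering vs. competitive exclusion) and the habitat
generalist/specialist structure of the taxa involved.

It is aimed at microbial ecologists with a rarefiable OTU count table, a
sample metadata table (month, coordinates, environmental variables) and a
rooted phylogeny of the OTUs.

## Statistics implemented

* **Net relatedness index.** For a community with observed mean pairwise
  patristic distance MPD, against a null of richness-matched random draws
  from the species pool:

  `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)`

  Positive NRI = phylogenetic clustering (habitat filtering); negative =
  overdispersion (competitive exclusion). Two-tailed rank significance with
  the (r+1)/(n+1) correction.

* **Mantel partitioning.** With Bray–Curtis community distances BC,
  z-scored-Euclidean environmental distances E and Euclidean spatial
  distances S: simple Mantel tests `[E] = r(BC, E)` and `[S] = r(BC, S)`,
  and partial Mantel tests `[E|S]` and `[S|E]` using the first-order
  partial correlation `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1-r_xz²)(1-r_yz²))`,
  with one-sided permutation p-values. The significance pattern of the two
  partial tests classifies each cell: `[E|S]` only → SS; both → SS+ME;
  `[S|E]` only → NM/PD; neither → UD; not computable → NF.

* **Levins' niche breadth.** For OTU *j* with read proportions `p_ij`
  across the *N* samples, `B = 1 / Σ_i p_ij²` ∈ [1, N]; OTUs are binned
  into B < 3, 3–6, 6–10 and B > 10 classes, and each bin's community
  variation is re-partitioned into environmental and spatial components
  (reported as 100·r²), with an OLS regression of explained variance on
  mean B.

* **Synthetic metacommunities.** `simulate_metacommunity()` generates OTU
  tables + metadata + phylogeny under a known regime (SS / ME / PD / NM),
  with Brownian-evolved niche optima, controllable generalist/specialist
  niche widths and a dispersal kernel, so the whole pipeline can be
  validated against ground truth.

## Worked example

Simulate a species-sorting scenario (13 stations × 7 months, 2500
reads/sample), partition the variation, and classify:

```r
library(metacomm)
sim <- simulate_metacommunity(scenario_config(regime = "SS", seed = 42))
t  <- sim$otu; md <- sim$metadata
bc <- bray_curtis(t); de <- env_distance(md); ds <- spatial_distance(md)
E  <- mantel_test(bc, de, n_perm = 999, seed = 1)
S  <- mantel_test(bc, ds, n_perm = 999, seed = 2)
ES <- partial_mantel(bc, de, ds, n_perm = 999, seed = 3)
SE <- partial_mantel(bc, ds, de, n_perm = 999, seed = 4)
classify_metacommunity(E, S, ES, SE)
```

```
simple Mantel: r = 0.9674, p = 0.001 (n = 91, 999 permutations)   # [E]
simple Mantel: r = 0.0068, p = 0.394 (n = 91, 999 permutations)   # [S]
partial Mantel: r = 0.9674, p = 0.001 (n = 91, 999 permutations)  # [E|S]
partial Mantel: r = 0.0358, p = 0.13 (n = 91, 999 permutations)   # [S|E]
metacommunity class: SS (alpha = 0.05)
```

Environment explains community variation independent of space
(`[E|S]` r = 0.97, p = 0.001) while space adds nothing beyond environment
(`[S|E]` p = 0.13): species sorting, as simulated. The niche-breadth
analysis on the same data:

```r
binned <- bin_by_breadth(levins_b(t), t = t)
bv <- breadth_partition_analysis(t, md, binned, n_perm = 199, seed = 5)
bv[c("bin", "n_otus", "mean_B", "r_E", "p_E", "var_expl_E_pct")]
breadth_regression(bv)[c("slope", "r_squared", "p_value")]
```

```
   bin n_otus mean_B   r_E   p_E var_expl_E_pct
1   <3     23   1.57 0.304 0.005           9.23
2  3-6     20   4.05 0.400 0.005          16.00
3 6-10     22   7.84 0.421 0.005          17.71
4  >10    127  50.89 0.967 0.005          93.49
slope 1.70, R2 0.998, p 0.00119
```

Environmental control rises steeply with niche breadth: the generalist
B > 10 bin is strongly environmentally structured (93% of its variation
explained) while the specialist B < 3 bin is only weakly so (9%) — the
generalists carry the biogeographical signal.

One-command equivalent: `run_pipeline(pipeline_config(simulate =
scenario_config(regime = "SS", seed = 42), out_dir = "out"))`, which writes
`nri.tsv`, `nri_by_month.tsv`, `battery.tsv`, `classes.tsv`,
`niche_breadth.tsv`, `bins_summary.tsv`, `bin_variance.tsv`,
`regression.tsv`, `manifest.json` and `run_log.txt`. A CLI wrapper lives at
`inst/cli/metacomm.R`.

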