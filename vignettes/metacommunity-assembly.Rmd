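---
title: "Inferring metacommunity assembly from OTU surveys: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring metacommunity assembly from OTU surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metacomm` implements a complete inference chain for microbial
metacommunity analysis: rarefaction, community/environmental/spatial
distances, the net relatedness index (NRI), Mantel-based variance
partitioning with a rule-based metacommunity classifier, Levins'
niche-breadth profiling, and a ground-truth simulator. This vignette
explains the statistical models, the defaults and why they were chosen,
and the places where the design was genuinely open.

## The data model

Three inputs, joined on sample identifiers:

* an **OTU table** — integer read counts, samples × OTUs, plus one
  taxonomy string per OTU;
* **sample metadata** — month label, latitude/longitude (decimal degrees),
  and a fixed set of environmental variables (salinity [PSU], temperature
  [°C], chlorophyll *a* [µg/L], NH4+, NO3-, PO43-, SiO4 [µM]);
* a rooted **phylogeny** of the OTUs with branch lengths
  (substitutions/site). Tips may be a superset of the table's OTUs; the
  reverse is an error at analysis time.

Sample-id set mismatches abort the pipeline with the full symmetric
difference, before any statistics run.

## Rarefaction

Counts are subsampled **without replacement** (multivariate
hypergeometric) to a common depth, per sample, under a caller-supplied
seed; samples below the depth are dropped and logged, and OTUs left with
zero reads are pruned. Without-replacement subsampling is the standard
choice for pyrosequencing-era read counts; the default depth of 2500
reads/sample reflects common practice for such surveys. Analyses
downstream (Bray–Curtis, niche breadth) use the rarefied counts; equal
depths make counts and proportions equivalent up to scale, so no further
transformation (square root, Hellinger) is applied.

Whether to rarefy before or after subsetting to a taxonomic group is not
determined by first principles; `metacomm` rarefies the full table once
and then subsets, so that all group-level analyses see the same reads.

## Distances

* **Community**: Bray–Curtis, `d(x,y) = Σ|x_i − y_i| / Σ(x_i + y_i)`.
  Two all-zero samples make the statistic 0/0 and are an error; single
  all-zero samples are dropped per analysis cell.
* **Environmental**: Euclidean over z-scored variables (default). The
  seven variables have incommensurable units; without standardization the
  micromolar nutrients would dominate. A variable with zero variance
  cannot be z-scored and is reported by name as an error.
* **Spatial**: Euclidean on raw (latitude, longitude) degrees by default,
  mirroring how transect studies commonly phrase "Euclidean distances of
  … latitude and longitude"; haversine great-circle distances (km,
  R = 6371 km) are available by flag. On a ~100 km transect the two are
  monotonically equivalent, and Mantel correlations are insensitive to
  monotone rescaling of a nearly 1-D configuration.

All distance matrices are validated: symmetric within 1e-12, exactly zero
diagonal, non-negative, uniquely labeled.

## Net relatedness index

For a sample's detected OTUs, MPD is the unweighted mean patristic
distance over unordered pairs (abundance weighting is available but off by
default, since presence-based MPD is the conventional NRI basis). The null
distribution is the MPD of `n_null` (default 999) richness-matched uniform
draws from the **species pool**; NRI is the negated z-score. Significance
is two-tailed at 0.025 per tail using rank probabilities with the
(r+1)/(n+1) correction. Exhaustive enumeration of all subsets replaces
sampling when feasible (≤ 10,000 combinations) and is the oracle the
sampled null is tested against.

Open choices, and what was decided:

* **Pool** — all OTUs of the rarefied table (not per-month pools). A
  single dataset-wide phylogeny implies a single dataset-wide pool;
  per-month pools would ask a subtly different question (clustering
  *within* the month's colonists rather than within the region's).
* **Null model** — richness-preserving uniform draws, equivalent to
  taxa-label shuffling for unweighted MPD. No occurrence-frequency
  weighting is applied.
* **Degenerate nulls** (member set = pool, or a star phylogeny) yield
  `sd = 0`; NRI is reported as NaN with an explicit `degenerate` flag
  rather than an error, and such samples are excluded from monthly
  summaries.

A caveat established by the package's own calibration tests: with very
small pools the rank test is conservative (ties between the observed and
resampled subsets inflate both tail probabilities); with pools of a few
dozen taxa the nominal 5% two-tailed rate is recovered.

## Mantel partitioning and the classifier

The Mantel statistic is Pearson's r over the lower-triangle entries; the
permutation null simultaneously permutes rows and columns of the first
matrix (default 999 permutations), one-sided in the "greater" direction —
positive distance correlation is the only ecologically interpretable sign
here. The partial statistic is the first-order partial correlation; the
permutation scheme permutes the **raw** first matrix and recomputes the
partial statistic (Legendre-style), the simplest defensible choice.

The battery runs all four tests — [E], [S], [E|S], [S|E] — for every cell
of {all months, each month} × {all taxa, each of seven groups:
Actinobacteria, Alpha-, Beta-, Gammaproteobacteria, Bacteroidetes,
Cyanobacteria, Verrucomicrobia; phylum-level labels except the
proteobacterial classes}. Cells with fewer than 4 usable samples, an
unmatched taxon, or degenerate distances are reported NF with a reason; no
multiple-testing correction is applied across cells by default (raw
per-test significance is what the classifier consumes).

The classifier is a pure function of the two partial p-values at
`alpha = 0.05` (p ≤ α counts as significant):

| [E\|S] | [S\|E] | label |
|--------|--------|-------|
| sig    | ns     | SS    |
| sig    | sig    | SS+ME |
| ns     | sig    | NM/PD |
| ns     | ns     | UD    |

NM and PD cannot be separated by these four tests alone — both predict
spatial signal independent of environment; distinguishing them needs
dispersal surrogates that co-occurrence surveys do not provide. The merged
NM/PD label makes that explicit.

## Levins' niche breadth

`p_ij` is the proportion of OTU *j*'s reads found in sample *i* (each
OTU's counts normalized **across samples**), and `B = 1/Σ p_ij²`. This is
the classical formulation over habitat states and the only reading that
bounds B in [1, N] — B = 1 for a single-site OTU, B = N for a perfectly
even one. B is invariant to scaling an OTU's counts and to sample order; B
is computed on rarefied counts, since unequal depths would distort the
proportions.

Bins follow the conventional generalist/specialist partition with fixed
boundary rules, `[1,3) [3,6) [6,10] (10,∞)` — the boundary values 3 and 6
go up, 10 stays in "6–10" (labels use ASCII hyphens in all outputs). For
each bin the table is subset to the bin's OTUs, samples without bin reads
are dropped, and [E]/[S] Mantel tests are run; "explained variance" is
reported as 100·r² with the signed r and p alongside, so either convention
is recoverable. The breadth regression is ordinary least squares of the
per-bin environmental explained variance on the per-bin mean B over the
four all-bacteria bins (per-group bins can be added as points by the
caller); it needs at least three non-NF bins.

## The synthetic generator: what it emulates, and what not

`scenario_config()` states the simulated world once: 13 stations × 7
months (April–October, 91 sample slots, optionally subsampled to 63),
2500 reads per sample, 200 OTUs. A **latent environmental axis** is the
sum of a linear south–north gradient (amplitude 1.0), a seasonal sine
peaking mid-summer (amplitude 1.5), and station-by-month noise (sd 0.8);
the seven emitted variables are linear maps of the axis with 5%
measurement noise. Niche optima evolve as a Brownian trait on a random
coalescent phylogeny, blended with independent noise via `phylo_signal`
(default 0.8). 30% of OTUs are generalists (niche width 3.0, 20× base
abundance — the common "core" taxa); specialists are narrow (width 0.4)
and rare. Reads are multinomial at the stated depth.

Regimes:

* **SS** — expected abundance ∝ Gaussian niche response to the local
  latent value.
* **ME** — a 50/50 blend of the local SS response with kernel-weighted
  immigration from the *time-averaged* neighboring source fields
  (exponential kernel, scale 1.5 stations). A pure within-month
  convolution of the SS response was tried first and rejected: smoothing a
  smooth gradient response merely widens niches and leaves no detectable
  spatial signal independent of environment. Immigration from persistent
  source populations is the ecologically intended meaning of mass effect
  and produces the [S|E] signature.
* **PD** — per-OTU exponential dispersal profiles around random source
  stations, constant over months, no environmental dependence.
* **NM** — one lognormal species-abundance distribution everywhere;
  sampling noise only.

The coalescent tree (rather than a pure-birth one with i.i.d. branch
lengths) is deliberate: a single Brownian realization on a
random-splitting tree correlates so weakly with patristic distance that
even perfectly environment-filtered communities show no NRI signal;
coalescent trees concentrate divergence on long shared interior branches
and give traits clade structure, which is the regime NRI is designed to
detect.

Effect-size defaults were calibrated once, against the package's own
recovery criteria (50 seeds per regime at 199 permutations), and then
frozen; they are not per-analysis tuning knobs.

What the generator does **not** emulate: temporal autocorrelation within
stations (months are exchangeable given the seasonal mean), overdispersed
(Dirichlet-multinomial) read sampling, taxonomy–niche association
(taxonomic groups are assigned independently of niche parameters),
spatially 2-D designs, and sequence-level artifacts (chimeras, clustering
error). A green recovery test therefore establishes that the inference
chain detects the stated signals at realistic survey sizes — not that it
is robust to every failure mode of real amplicon data.

## Numerical conventions

* Distance symmetry tolerance 1e-12; diagonals exactly zero.
* Permutation p-values use the +1 correction and are never zero;
  `n_perm = 0` is allowed where only the statistic is needed and yields
  `p = NA` (the classifier refuses NA).
* Counts must be integer-valued within 1e-8 (guards against silent
  truncation of proportions passed in error).
* All randomness flows from caller-supplied seeds; per-stage seeds are
  derived from the pipeline seed by fixed offsets so stages can be rerun
  in isolation. Reruns are byte-identical.
* The pipeline config is an R list or JSON file (JSON rather than YAML
  keeps the dependency set to packages universally available).

## Known limitations

* Mantel partitioning has limited power and is not a variance
  decomposition in the ANOVA sense; db-RDA-style partitioning is out of
  scope by design.
* The classifier inherits the miscalibration of its inputs: with strongly
  saturated community distances (steep gradients, narrow niches) the
  partial tests can register curvature as spurious spatial signal. The
  simulator's calibrated defaults avoid that region; real data may not.
* NM vs PD are reported merged, and "ME" is always reported jointly with
  SS (the [S|E]-only pattern is labeled NM/PD).
* Niche-breadth bins with very few OTUs or occupied samples go NF rather
  than producing unstable estimates; the regression then needs three
  non-NF bins.
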