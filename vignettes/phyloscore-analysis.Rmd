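---
title: "Phyloscore analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phyloscore analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloscore)
```

## The problem

Community-level phylogenetic null models ask whether two microbial
communities are more or less phylogenetically similar than expected by
chance, and read the answer as the signature of an assembly process:
lower-than-random phylogenetic turnover indicates homogeneous environmental
selection, higher-than-random turnover variable selection, and
phylogeny-blind compositional shifts indicate dispersal. These statistics
average over all taxa, so they cannot say *which* parts of the phylogeny
drive the pattern. Phyloscore analysis closes that gap: it assigns a
turnover z-score to every (ASV, sample pair) event and then asks, via
phylofactorization, whether monophyletic clades carry systematically low
scores (HoS clades — their members are replaced across samples by close
relatives, the signature of clade-wide niche occupancy) or systematically
high scores (HeS clades — confined to subsets of samples). HoS clades are
subsequently screened for putative microdiversity: tight nearest-taxon
distances and spatial replacement among >97%-similar sub-taxa.

## The phyloscore

For ASV $i$ present in sample $j$ and absent from sample $k$ (richness
$N_k$), let $d_{i,j,k}$ be the patristic distance from $i$ to its nearest
neighbour among the taxa present in $k$. The null model draws $N_k$ taxa
uniformly without replacement from the regional pool minus $i$, records the
nearest distance, and repeats $M$ times. The phyloscore is

$$z_{i,j,k} = \frac{\log d_{i,j,k} - \langle \log d^0_m \rangle_m}{\sigma^0},$$

with natural logs; $\langle\cdot\rangle_m$ and $\sigma^0$ are the mean and
standard deviation of the log-transformed null minima. Negative scores mean
$i$'s replacement is closer than chance. Scores depend on the
presence/absence pattern and the distance matrix only — abundances never
enter (the suite asserts invariance under abundance rescaling).

Two implementation facts are worth knowing:

* **Exact null by rank distribution.** The minimum of a uniform random
  $N$-subset of the $P$ pool distances is the $r$-th closest with
  probability $\binom{P-r}{N-1}/\binom{P}{N}$. `exhaustive_null()` uses
  this identity to return the *exact* null moments at any pool size (a
  literal subset-enumeration mode is kept as an independent cross-check),
  and `phyloscore(..., exact = TRUE)` gives the noise-free z.
* **Variance-reduced Monte Carlo.** The default sampler draws the $M$
  minima by inverse-CDF sampling of the same rank distribution with
  stratified uniforms — one uniform per probability stratum. The draws are
  marginally identical in law to drawing subsets, but the estimated moments
  converge at $O(1/M)$ rather than $O(1/\sqrt M)$, which keeps $M = 100$
  (the default) both faithful to the method's specification and tightly
  reproducible. `sampling = "simple"` restores plain iid draws.

Null means and standard deviations use population moments (denominator
$M$), so the Monte-Carlo z converges exactly to the exhaustive z; on the
three-taxon worked tree (`((A:1,B:1):1,C:2);`, focal A, recipient {B}) the
exhaustive z is exactly $-1$.

**Degenerate inputs.** Distances are floored at half the smallest positive
patristic distance before logging, so zero-length placements never reach
$\log$; the count of floored records is attached to the score table.
Records whose null spread is zero are flagged `sd_zero` and excluded from
aggregation with a reported count.

**Null pool.** The paper-style default pool is *regional* (all ASVs in the
validated dataset minus the focal); `pool = "pair"` restricts it to the
taxa of the two compared samples.

## Aggregation and phylofactorization

Per ASV the package always emits the sum (*total*, the default input to
phylofactorization — it up-weights ASVs that are frequently replaced), the
mean, the median, the record count and the mean/sd quotient, so the clade
search can be re-run cheaply on any of them.

`phylofactorize()` sequentially cuts the tree edge maximizing the absolute
equal-variance two-sample t statistic between the scores on the two sides
of the edge *within the bin the edge lives in*. After $f$ cuts the tips are
partitioned into $f+1$ bins. Details fixed by design:

* both sides of a candidate edge need at least 2 scored tips (the pooled t
  does not exist otherwise);
* objective ties are broken by the smallest edge index — the procedure is
  fully deterministic given scores;
* the stopping rule is open in the method's description, so the package
  stops when the best edge's p-value, Bonferroni-corrected by the number of
  admissible edges tested in that iteration, exceeds `alpha` (default
  0.05), with `max_factors` as a hard cap. The correction is conservative
  (the per-edge tests are strongly dependent), which the type-I calibration
  test confirms;
* a clade is HoS when its mean score is below its complement's, HeS
  otherwise;
* consensus taxonomy reports the deepest rank at which at least 95% of the
  classified clade members agree.

## Community-level machinery

βMNTD is the abundance-weighted mean, over taxa present in exactly one
sample of a pair, of each taxon's nearest patristic distance to the other
sample's members (weights: the focal taxon's relative abundance in its own
sample, renormalized over the contributing set; `weighting = "presence"`
gives the simple mean). βNTI compares the observed βMNTD to a tip-shuffling
null. The package's default null relabels the two communities
*independently* per replicate: this randomizes membership including the
overlap of the pair, so two identical communities — whose turnover is as
low as it can be — score strongly negative, as the threshold logic
requires. The classic single shared relabeling (`null_model = "shared"`)
is also available; it preserves overlap and leaves identical communities
undefined, which is why it is not the default here.

RC_Bray rebuilds each sample at its observed richness (taxa drawn with
probability proportional to occupancy) and fills to the observed total
count (multinomial, probabilities proportional to regional relative
abundance, with replacement), then locates the observed Bray-Curtis
dissimilarity in the null distribution with ties at half weight. Integer
totals are required for the fill; relative-abundance tables degrade to a
richness-only null. Process calls use strict thresholds: βNTI < −2
homogeneous selection, > +2 variable selection, otherwise RC_Bray < −0.95
homogenizing dispersal, > +0.95 dispersal limitation, else undominated;
boundary values fall through.

Null replicate counts are configurable; 999 is the default (enough
resolution for the ±2 and ±0.95 cutoffs).

## Microdiversity screen

* `ntd()` — per-tip nearest taxon distance (substitutions/site), invariant
  under rerooting.
* `pairwise_identity()` — global Needleman–Wunsch alignment with affine
  gaps (match +1, mismatch −1, gap open −2, gap extend −0.5); identity =
  matching columns / alignment columns excluding terminal gaps × 100
  (end-gap-free identity suits amplicons of unequal trimming). Argument
  order is canonicalized so the reported identity is symmetric even when
  optimal alignments tie.
* `beta_nearest_similarity()` — for each focal ASV and each sample lacking
  it, the identity to the phylogenetically nearest present ASV (ties
  averaged); per-ASV value = median over samples. The fraction of
  *replacement events* with identity strictly above 97 is the
  putative-ecotype criterion.
* `clade_rarefaction()` — expected distinct clade ASVs under hypergeometric
  subsampling of the clade's pooled counts; the saturation check against
  inadequate-sampling bias.
* `depth_vs_ntd()` — the diagnostic for NTD-vs-depth bias. Per-tip root
  distance vs NTD (`level = "tip"`) is the interface used on real data; on
  uniform-attachment random trees the weak negative tendency appears at the
  *clade* level (root-to-MRCA distance vs median member NTD,
  `level = "clade"`), which is how the package's random-tree test measures
  it. Optional detrending of log NTD on root distance is off by default.

## Niche conservatism

Niche optima are abundance-weighted means of each environmental variable
over the samples where an ASV occurs (weighted medians available); niche
distances are euclidean on per-variable z-scores, hence invariant to affine
transformations of the inputs. The Mantel correlogram partitions the
phylogenetic distances into equal-width classes (Sturges' rule on the pair
count by default), computes per class the correlation between class
membership and niche distance, signed so that positive r means within-class
niche similarity, and attaches permutation p-values (row/column
permutations of the niche matrix shared across classes, one-tailed toward
the observed sign) with progressive Holm correction. Classes in the upper
half of the distance range that exclude some taxa are not tested (the
standard correlogram cutoff) and classes with under 20 pairs are flagged
low-power. The engine is vectorized so the calibration properties can be
run hundreds of times; its r values are cross-checked against the
reference implementation in vegan on shared break points.

A positive, significant r in the shortest class — verified here on
Brownian-motion traits — is the prerequisite for all nearest-taxon null
models above.

## What the synthetic generator emulates — and what it does not

`plant_hos_clade()` reproduces the occupancy signature that defines an HoS
clade: the clade as a whole occupies `clade_occupancy` of samples (default
1.0) while each member occupies only `per_asv_occupancy` (default 0.3), so
members are continually replaced by fellow members; at least one member is
forced into each clade-occupied sample (a small upward bias on per-member
occupancy, within the generator's ±0.1 self-check tolerance). Background
taxa are present iid at `background_occupancy = 0.1`. The background is
deliberately *sparse*: the phyloscore contrast requires the presence rate
of a taxon's close relatives to exceed the null inclusion rate $N_k/P$, so
a background as prevalent as the clade members would cancel the planted
signal by construction — and sparse occupancy is also what real ASV
occupancy distributions look like. Abundances are lognormal(0, 1); the
phyloscore is abundance-blind, so this matters only for the
community-level statistics. `plant_hes_clade()` confines the clade to one
sample group. `compress_clade()` shrinks within-clade branches to create
microdiverse structure, `evolve_sequences()` evolves JC69 sequences along
the tree (closed-form expected identity anchors the tests), and
`bm_traits()` provides phylogenetically conserved niche traits.

What the generator does **not** emulate: sequencing error and chimeras,
compositional count noise, uneven sampling depth, correlated occupancy
across samples (spatial structure), and real taxonomic label structure.
Passing the planted-recovery tests therefore shows that the inference
chain is correct and well calibrated under its own model; it does not show
robustness to upstream artifacts, which must be handled before input (the
prevalence filter `filter_min_samples()` and the rarefaction check are the
in-package guards).

## Problem sizes used by the test-suite

The suite exercises the stack at desk scale, chosen to make every
stochastic property measurable in minutes: exhaustive-oracle equivalence on
10-taxon pools; planted-clade recovery over 50 runs at 500 tips, 30
samples, 40-tip clades, M = 100; null calibration over ~25k records pooled
from 6 independent 150-tip matrices and 200 type-I runs on 60-tip trees;
the microdiversity screen over 20 runs at 100 tips; conservatism recovery
over 20 runs at 200 tips with 199 permutations and 200 shuffled-trait runs
at 50 tips with 99 permutations. `scripts/acceptance.R` re-runs the same
machinery end to end on a fresh seed.

## Known limitations

* Phyloscores inherit the resolution of the input tree; short amplicons
  limit topology near the tips, which affects which ASV within a clade is
  the nearest relative but not the clade-level inference.
* Tips adjacent to a strongly selected clade (whose nearest relatives are
  that clade) earn genuinely negative scores and occasionally join the
  recovered factor — a property of the method, visible in the planted
  simulations as occasional one-to-two-tip overshoots.
* The equal-variance t objective treats aggregated scores as plain
  observations; ASVs with few records are noisier than their weight
  reflects (the emitted `n_pairs` and `mean_over_sd` metrics let users
  re-factor on alternatives).
* RC_Bray needs count-like tables for its abundance fill; purely relative
  tables lose the abundance component of the null.
* "Putative" microdiversity is a screen, not a demarcation: low NTDs and
  >97% replacements can also arise from ecologically neutral fine-scale
  diversification, so hits warrant genomic or phenotypic follow-up.
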