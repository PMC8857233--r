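# phyloscore

Clade-wise phylogenetic turnover analysis for microbial communities.

Community-level null models (βMNTD/βNTI, Raup–Crick) tell you *whether* a
pair of microbiome samples is assembled by homogeneous selection, variable
selection or dispersal — but not *which clades* drive the pattern.
`phyloscore` implements **phyloscore analysis**: a per-ASV, per-sample-pair
z-score of phylogenetic turnover, aggregated along the tree by
phylofactorization to identify monophyletic clades under homogeneous
(HoS) or heterogeneous (HeS) ecological selection, followed by a screen of
those clades for putative microdiversity. It is aimed at microbial
ecologists working from an ASV table, a phylogenetic tree, and optionally
representative sequences and sample metadata.

## The statistic

For ASV *i* present in sample *j* and absent from sample *k* (richness
N<sub>k</sub>), let d<sub>i,j,k</sub> be the patristic distance from *i* to
its nearest neighbour among the taxa present in *k*. Against a null that
draws N<sub>k</sub> taxa uniformly from the regional pool minus *i*
(M = 100 draws by default), the phyloscore is

    z_ijk = ( log d_ijk − ⟨ log d0_m ⟩ ) / σ0

where the mean and standard deviation are taken over the log-transformed
null nearest distances. Negative z: *i* is replaced by a closer relative
than chance. Per-ASV totals (sums of z across all sample pairs) feed a
phylofactorization whose objective is the absolute equal-variance
two-sample t statistic between the scores on the two sides of each tree
edge; clades with distinctly negative totals are HoS clades. The package
also provides the community-level βNTI / RC<sub>Bray</sub> framework with
strict-threshold process assignment (−2/+2, −0.95/+0.95), nearest-taxon
distances and β-nearest-ASV nucleotide similarity with the >97% sub-taxon
criterion, per-clade rarefaction, niche optima with a Mantel-correlogram
conservatism check, and a synthetic-data generator with planted clade
structure.

## Worked example

Simulate a 150-tip community with a planted 25-tip HoS clade (short
internal branches, clade-wise occupancy 1.0, per-ASV occupancy 0.3, sparse
background), then run the full pipeline:

```r
library(phyloscore)
set.seed(7)
tree  <- random_tree(150)
clade <- pick_clade(tree, 25)
tree  <- compress_clade(tree, clade, 0.05)   # microdiverse: tight branches
sim   <- plant_hos_clade(tree, clade, n_samples = 20)
seqs  <- evolve_sequences(tree, length = 250)

res <- run_pipeline(tree, sim$comm, seqs = seqs, M = 100,
                    turnover_reps = 199, seed = 42, verbose = FALSE)
print(res$factors)
#> phylofactorization: 2 factor(s), stop reason: alpha
#>   index n_clade    t_stat p_bonferroni direction consensus_taxonomy
#> 1     1      23 -14.19711 1.041645e-23       HoS               <NA>
#> 2     2       6   3.69824 4.009503e-02       HeS               <NA>
jaccard_index(res$factors$clades[[1]], sim$truth$planted_clade_tips)
#> [1] 1
print(res$microdiversity[[1]])
#> clade microdiversity report (23 tips)
#>   NTD median clade/background: 0.005725 / 0.1241  (Wilcoxon p = 5.91e-13)
#>   frac > 97% clade/background: 0.915 / 0  (Wilcoxon p = 6.84e-167)
```

Factor 1 recovers the planted clade exactly (Jaccard 1.0; the planted
clade here has 23 tips): its members' total phyloscores are far below the
background (t = −14.2), direction HoS. The microdiversity report shows the
two signatures of putative microdiversity: within-clade nearest-taxon
distances ~20× shorter than background, and 91.5% of spatial replacements
occurring between ASVs more than 97% identical (background: 0%).

File-based inputs work through `read_newick()`, `read_community()`,
`read_sequences()`, `read_taxonomy()`, `read_metadata()` and
`to_absolute()` (cell-count scaling); a thin command-line wrapper lives at
`inst/scripts/phyloscore-cli.R`.

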