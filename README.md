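# ecodelin

Delineating forest ecosystems at national scale from tree inventory plots —
and extending them wall-to-wall with an object-oriented random-forest
classifier.

`ecodelin` is aimed at community ecologists and forest-monitoring teams who
have (i) a network of inventory plots with stem-level records (species, DBH,
subplot) and (ii) per-segment environmental/spectral summaries of the forest
cover, and who want a reproducible path from those tables to a map-ready set
of floristically defined ecosystems, the species assemblages that
characterise them, and the old-growth/secondary forest make-up of each one.
Every function takes a data frame and returns a tibble, so stages chain with
the pipe; a synthetic-inventory generator with known ground truth makes the
whole pipeline testable end to end.

## The method

1. **Dominance screening (IVI).** For species *s* in a plot, the Importance
   Value Index averages relative density (% of stems), relative dominance
   (% of basal area, BA = π(DBH/200)²) and relative frequency (% of
   subplot-presence counts), so per-plot IVI totals are 100. Species with
   IVI ≥ 5% are the plot's dominant canopy species.

2. **Turnover clustering.** Between sites with shared abundance
   *A* = Σ min(x₁, x₂) and exclusive abundances *B*, *C*, the
   balanced-variation (turnover) component of Bray–Curtis dissimilarity is

   β = min(B, C) / (A + min(B, C)),

   which scores compositional replacement while ignoring nestedness. Sites
   are clustered by UPGMA over many random orderings of the dissimilarity
   matrix (order matters only through ties); the tree with the best
   cophenetic correlation is kept. The number of clusters is chosen by an
   elbow rule on `pc_distance`, the between-cluster share of total
   dissimilarity, and single-site clusters are merged into or excluded from
   the main clusters by Simpson similarity against a 50% threshold.

3. **Species contributions and the cluster network.** The test value

   ρᵢⱼ = (μᵢⱼ − μ) / √( ((n − nⱼ)/(n − 1)) · σ²/nⱼ )

   standardises a species' over/under-representation in cluster *j* by the
   exact SD of a without-replacement sample mean; species with ρ ≥ 1.96
   (one-tailed 2.5%) form the contributive assemblage *Aⱼ*. Normalising the
   positive parts of ρ per species and averaging them over *Aⱼ* gives the
   row-stochastic interaction matrix λ, whose diagonal is cluster
   specificity and whose off-diagonal entries measure shared assemblages;
   the network is projected onto per-cluster medians of elevation and
   annual precipitation.

4. **Ecosystem model.** Segments summarised by per-variable q25/q50/q75
   inherit the cluster of the plot they contain (clusters with < 15
   labelled segments are dropped); features pass recursive feature
   elimination with a random forest and greedy |r| > 0.7 collinearity
   pruning; the classifier is evaluated with stratified 10-fold CV
   (row-percentage confusion matrix, per-class F1, support-weighted F1,
   macro F1), interrogated with response-permutation variable importance
   (p = (1 + #{null ≥ obs})/(nperm + 1)) and partial dependence, and then
   predicts ecosystems for unsampled segments.

5. **Forest-type composition.** OGF/SF shares per in situ cluster and per
   predicted ecosystem, with per-ecosystem |Δ OGF| and dominance-inversion
   flags between the two views.

## Worked example

Everything below runs on a synthetic landscape with 3 planted clusters
(54 plots) and a 30%-shared background flora:

```r
library(ecodelin)

cfg <- pipeline_config(
  sim = sim_config(
    n_clusters = 3, sites_per_cluster = c(20, 18, 16),
    species_per_cluster_pool = 6, n_shared_species = 4,
    trees_per_plot_mean = 40, abundance_dispersion = 3,
    n_feature_variables = 8, pixels_per_segment = 15, seed = 42
  ),
  n_randomizations = 50, folds = 5, rfe_sizes = c(4, 8),
  n_permutations = 50, num_trees = 200, seed = 42
)
res <- run_pipeline(cfg, out_dir = "run1")

res$clustering
#> Bioregionalisation: 3 clusters over 54 sites
glance(res$clustering)
#> # A tibble: 1 × 6
#>       k n_sites n_merged n_excluded cophenetic_corr pc_distance
#>   <int>   <int>    <int>      <int>           <dbl>       <dbl>
#> 1     3      54        0          0           0.870       0.799
res$interaction
#> Cluster-interaction matrix over 3 clusters
#>   mean specificity: 100.0% (range 100%-100%)
res$fit
#> Ecosystem random forest: 3 classes, 1 features, 5 -fold CV
#>   F1 = 1.000, macro F1 = 1.000
res$comparison
#> Forest-type composition: mean |dOGF| = 9% +/- 7% over 3 ecosystems
#>   dominant type inverts for: 2
```

Reading the output: the elbow rule recovered the planted k = 3 with a
cophenetic correlation of 0.87 and 80% of compositional dissimilarity
between clusters; each cluster's contributive assemblage is fully specific
to it (λ diagonal = 1, so the network has no edges above the 5% rule); the
segment classifier separates the three ecosystems perfectly after feature
selection collapsed the redundant elevation quantiles to one; and the
plot-based versus pixel-based forest-type compositions differ by 9% ± 7%
in OGF share, with cluster 2's dominant type flipping between the two
views — the kind of disagreement the composition comparison is built to
flag. `run1/` holds every stage table (CSV), the dendrogram (Newick), the
interaction network (GraphML) and a JSON provenance manifest; rerunning
with the same config reproduces the manifest digests exactly.

Individual stages are ordinary functions on data frames
(`compute_ivi()`, `select_dominant()`, `bray_turnover()`,
`upgma_best_tree()`, `select_k_elbow()`, `resolve_singletons()`,
`test_values()`, `interaction_matrix()`, `label_segments()`,
`select_features_rfe()`, `fit_evaluate()`, `permutation_importance()`,
`partial_dependence()`, `composition_by_cluster()`, …), with `tidy()` /
`glance()` methods for fitted objects and `autoplot()` / `plot_network()`
displays for the pc-curve, λ heatmap, confusion matrix, importance,
partial dependence and the environmental network projection.

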