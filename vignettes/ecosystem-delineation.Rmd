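---
title: "Delineating forest ecosystems from inventory plots: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating forest ecosystems from inventory plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ecodelin` chains five analysis stages — dominance screening, turnover
clustering, contribution analysis, object-oriented classification and
forest-type composition — into one reproducible pipeline. This vignette
explains the statistical model behind each stage, the parameters that
matter and their defaults, the numerical conventions, what the synthetic
generator does and does not emulate, and the design choices made where the
methodology was genuinely open.

```{r setup}
library(ecodelin)
```

## Dominance screening with the Importance Value Index

Tropical inventories carry a long tail of rare species whose presence is
close to noise for ecosystem delineation. The IVI concentrates each plot's
signal on the species that structure its canopy. For species $s$ in a plot
we average three relative components, each summing to 100 within the plot:

$$\mathrm{IVI}_s = \tfrac{1}{3}\left(100\frac{N_s}{N} +
  100\frac{BA_s}{BA} + 100\frac{F_s}{\sum_t F_t}\right),$$

with $N_s$ stem counts, $BA_s = \sum \pi(\mathrm{DBH}/200)^2$ basal area in
m², and $F_s$ the number of subplots occupied. Two conventions matter:

* **Scale.** The classical index sums to 300 per plot; we divide by 3 so
  totals are 100 and a "5 % threshold" reads directly as 5 % of plot
  importance. The companion diagnostics (`ivi_retention()`) measure the
  cumulative IVI captured by a threshold, averaged per plot (plot-weighted
  mean, each plot counting equally regardless of stem count).
* **Relative frequency.** The denominator is the sum of subplot-presence
  counts over species — the Curtis–McIntosh convention — not the number of
  subplots; only this choice makes the component sum to 100 exactly.

The dominance filter is inclusive (`ivi >= threshold`), so boundary species
are retained. Records under 10 cm DBH are rejected at load: most national
inventories census smaller stems differently, and the method targets the
canopy community. Plots where no species reaches the threshold are dropped
with a warning rather than failing the run; they carry no dominance signal.

Threshold sensitivity is quantified with the Adjusted Rand Index between
clusterings run at different thresholds (`threshold_sensitivity()`), the
chance-corrected pair-counting agreement computed from the contingency
table.

## Turnover dissimilarity and order-randomised UPGMA

Compositional dissimilarity uses the balanced-variation (turnover)
component of abundance-based Bray–Curtis:

$$\beta = \frac{\min(B, C)}{A + \min(B, C)},$$

with $A$ the summed shared abundance and $B, C$ the abundances exclusive to
each site. Unlike the full Bray–Curtis index this ignores the nestedness
(abundance-gradient) part, so a small plot nested inside a rich one scores
0 and plot size does not masquerade as compositional change. Degenerate
conventions: identical sites → 0, disjoint sites → 1, and
$\min(B,C) = 0$ → 0 (pure nestedness).

UPGMA (average linkage) is order-sensitive only through ties in the
dissimilarity matrix, which are common with discrete abundance data. We
therefore build the tree on `n_randomizations` random orderings of the
sites (default 1000; ties broken by the lowest pair under the permuted
order) and keep the tree whose cophenetic distances best correlate with the
input matrix. Correlation ties keep the earliest tree, making the procedure
deterministic under a fixed seed. On tie-free matrices every ordering gives
the same topology, and the implementation is checked against
`stats::hclust(method = "average")` in the test suite.

The number of clusters is selected with an elbow rule on `pc_distance`,
the ratio of between-cluster dissimilarity to total dissimilarity: cutting
the tree at each $k$ in `k_range` (default $2$ to $\min(20, n-1)$; wide
enough to contain plausible cluster counts for inventories of a few hundred
plots) traces a non-decreasing curve, and the elbow is the point with
maximum perpendicular distance to the chord joining the curve's endpoints —
a parameter-free detector; the method itself does not prescribe one. A
curve with no interior elbow falls back to the smallest $k$ with a warning.

Single-site clusters are screened with Simpson similarity
($1 - \min(b,c)/(a+\min(b,c))$ on presence sets) between the isolated site
and each multi-site cluster's pooled species set. If the best similarity
reaches 50 % the site is merged there, otherwise excluded. The correction
for screening against $m$ candidate clusters is implemented as a
Bonferroni-style tightening of the similarity requirement to
$1 - (1 - t)/m$ (the allowed dissimilarity budget divided by the number of
comparisons). This is an interpretation: the methodology names a
correction but no explicit test statistic, so the rule is exposed as a
toggle (`n_comparisons_correction`) and every disposition is logged.

## Species test values and the interaction network

The contribution of species $i$ to cluster $j$ is the standardised test
value

$$\rho_{ij} = \frac{\mu_{ij} - \mu}
  {\sqrt{\frac{n - n_j}{n - 1}\cdot\frac{\sigma^2}{n_j}}},$$

where $\mu$ and $\sigma^2$ are the mean and *population* variance (divisor
$n$) of the species' abundances over all $n$ sites. The denominator is
exactly the standard deviation of the mean of $n_j$ sites drawn without
replacement from the site pool — the test suite verifies this against
exhaustive enumeration of all subsets up to $n = 8$ — so $\rho$ reads as a
z-score and $\delta = 1.96$ corresponds to a one-tailed 2.5 % Gaussian
level. The threshold is inclusive ($\rho \ge \delta$); constant species get
$\rho = 0$ rather than NaN since they carry no signal.

Normalised contributions $\hat\rho^+_{ij} = \rho^+_{ij} / \sum_k
\rho^+_{ik}$ use the positive part $\rho^+ = \max(\rho, 0)$ for **all**
clusters, while a species enters the network only through membership in
some contributive set $A_j = \{i : \rho_{ij} \ge \delta\}$. The wording of
the source methodology conflates "positive" and "significantly positive";
we default to the positive part (which keeps $\hat\rho^+$ rows well defined
and matches the cited network methodology) and expose the stricter
significant-only clipping as `clip = "significant"`. Species with no
positive contribution anywhere are dropped with a message.

The interaction matrix averages contributions over each cluster's
assemblage, $\lambda_{jj'} = |A_j|^{-1} \sum_{i \in A_j} \hat\rho^+_{ij'}$.
Rows are means of unit-sum rows, hence sum to 1 by construction — an
invariant asserted to $10^{-9}$ on every valid input. The diagonal is
specificity; off-diagonal entries above 5 % (strictly) become directed
network edges, and nodes are placed at per-cluster medians of two
environmental variables (defaults: annual precipitation vs elevation).

## Object-oriented classification

Segments are summarised by q25/q50/q75 of each variable's pixel samples
(linear-interpolation quantiles, `type = 7`). A segment containing a plot
adopts the plot's cluster on the assumption that the plot represents the
segment; segments linked to plots from conflicting clusters are excluded
(the source methodology never addresses conflicts), and clusters with fewer
than 15 labelled segments are dropped from training entirely — too thin to
cross-validate.

Feature selection is two-step. Recursive feature elimination refits a
random forest, dropping the least impurity-important variable until one
remains, which yields a full ranking; each candidate subset size (default
5–30) is then scored by stratified cross-validated F1 and the best size
wins (ties to the smaller). The ranking is produced once on the full
training set, as in the standard RFE implementations this mirrors; scores
for subset sizes are therefore mildly optimistic, which is acceptable
because they only pick a size, while headline performance comes from the
separate cross-validation below. Collinearity is then pruned greedily in
rank order: a variable correlated above |r| = 0.7 with an already-kept one
is dropped — a deterministic, logged stand-in for the expert judgement a
national study would apply.

Evaluation uses stratified 10-fold CV (folds shrink with a warning if the
smallest class is smaller), pooling out-of-fold predictions into a
row-percentage confusion matrix. Per-class F1 comes from the pooled
matrix; the aggregate "F1" is the support-weighted mean (on imbalanced
classes this sits well above the macro F1, the unweighted mean — reporting
both is deliberate). The forest is `ranger` with 500 trees by default,
single-threaded and seeded for bit-reproducibility.

Variable importance follows the response-permutation scheme: observed
importance is the forest's permutation (mean decrease accuracy — overall
and per class via casewise importance) and impurity (Gini) importance; the
null distribution refits the forest on label-permuted data
`n_permutations` times (default 100), giving
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perm}} + 1)$ — the
smallest attainable p-value with 100 permutations is $1/101$. Partial
dependence sweeps one variable over its observed range with all others held
at their observed values, reporting per-class mean probability and
log-odds (clamped at $10^{-6}$ to keep the transform finite on separable
data).

## Forest-type composition

Old-growth (OGF) versus secondary (SF) shares are counted per in situ
cluster (plots) and per predicted ecosystem (pixels); records without a
valid type are excluded from denominators, not imputed — real forest-cover
maps carry non-forest classes that are excluded the same way.
`compare_compositions()` reports per-ecosystem $|\Delta\,\mathrm{OGF}|$,
its mean ± SD, and flags ecosystems whose dominant type inverts between
the two views.

## The synthetic generator and what passing tests mean

`sim_config()` describes a planted landscape: K clusters, each with a
disjoint pool of dominant species plus a shared background pool; per-plot
abundances are Dirichlet-multinomial (the Dirichlet concentration
`abundance_dispersion` controls how oligarchic plots are, with the shared
pool given half the concentration mass of the cluster pool so planted
dominants dominate in expectation); DBH is lognormal truncated at 10 cm;
trees fall uniformly into subplots; environmental variables are Gaussian
around cluster means with pure-noise distractors filling the candidate set;
forest type is Bernoulli with a per-cluster SF probability. Defaults — 5
clusters of 30/22/16/10/6 plots, 8 pool + 10 shared species, 60 stems per
plot, dispersion 0.6, DBH meanlog 3.1 / sdlog 0.45, elevation 300–2300 m
(SD 150) and precipitation 1800–3800 mm/yr (SD 250) among 34 candidate
variables, SF probabilities 0.1–0.9, 40 pixels per segment — are desk-scale
analogues of a national campaign: unbalanced clusters, a heavy-tailed
flora, strong environmental gradients, and mostly-redundant candidate
features.

The generator does **not** emulate spatial autocorrelation, succession
dynamics, detection error, taxonomic drift between campaigns, or spectral
imagery; passing recovery tests therefore demonstrates the pipeline's
correctness and its behaviour under compositional and feature noise, not
robustness to those field realities.

Two benchmark regimes anchor validation:

* **Zero noise** — disjoint pools, no shared species, and
  `abundance_dispersion = 3` (even within-cluster abundances). Evenness is
  part of the *definition* of this regime: with disjoint pools,
  between-cluster turnover is exactly 1, and recovery is deterministic
  provided plots within a cluster share their pool, which heavy-tailed
  abundances can break by chance. Under this regime the pipeline must
  recover the planted partition exactly (ARI = 1), select the planted K,
  produce an identity λ, and classify segments with macro F1 = 1.
* **Moderate noise** — the same benchmark with exactly one factor changed:
  a shared background pool making up 30 % of the species. Holding
  everything else fixed isolates the shared-species effect; the median ARI
  over 20 seeds must stay at or above 0.9.

Benchmark problem sizes (54-plot landscapes, 25 tree randomisations, 10–50
importance permutations, 100–200 trees) are the package's choice of
smallest sizes at which the properties are stable; the pipeline defaults
remain at the field-standard values (1000 randomisations, 500 trees, 100
permutations).

## Numerical conventions and degenerate inputs

* Dissimilarities validated symmetric within $10^{-8}$ and in $[0,1]$;
  ultrametricity of cophenetic distances holds to machine precision.
* UPGMA heights are non-decreasing (average linkage is reducible); Newick
  export derives branch lengths from merge heights.
* `pc_distance` with a single site, a cluster spanning all sites in
  `test_values()`, an empty species set in `simpson_dissimilarity()`, an
  all-singleton partition in `resolve_singletons()`, and a missing feature
  column in `predict_segments()` are errors, not silent results.
* Medians follow the standard midpoint-of-middle-two convention; quantiles
  are `type = 7` everywhere.
* One global seed fans out to per-stage seeds through a fixed integer hash,
  so stages are individually reproducible and no two stages share a
  stream.

## Known limitations

* The elbow detector and the Bonferroni-style singleton rule are
  principled but non-unique readings of their under-specified sources;
  both are exposed as options and logged.
* RFE is not nested inside the outer CV (see above); with few segments and
  many correlated features the subset-size scores should be read as
  relative, not absolute.
* Per-class importance aggregates casewise permutation importance, which
  is noisier than the overall measure; its p-values inherit that noise.
* The pipeline consumes segment tables; segmentation itself (and any
  raster I/O) is upstream of this package.
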