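# salnet

Salient-network skeletons for structural brain connectivity.

## The problem

Structural MRI cohorts yield one dense weighted network per subject: the
brain is tiled into ~3000 mm^3 supervoxel boxes (the scale of the anatomical
structures affected early in Alzheimer's disease) and every pair of boxes is
linked by the Pearson correlation *r* of their voxel intensities. Dense
correlation networks are large, noisy, and expensive to compare across
subjects. `salnet` implements a reduction pipeline that keeps the
discriminative content while discarding most nodes and links:

1. **Topology threshold** — scan thresholds `r_thr` and keep the smallest
   one at which the networks jointly show scale-free structure (adjusted R^2
   of the OLS fit to the log-log degree histogram) and small-worldness
   `SW = (C/C_r) / (L/L_r)`, with Erdos-Renyi reference values
   `C_r = k̄/N'`, `L_r = ln N' / ln k̄`.
2. **High-salience skeleton** — with distances `D_ij = 1/w_ij`, the
   shortest-path tree `T(n)` of reference node `n` marks every edge on at
   least one minimum-distance path from `n`; edge salience is the fraction
   of trees containing the edge, `S = (1/N') Σₙ T(n)`. Salience is bimodal
   (values pile up at 0 and 1), so thresholding at `s ≥ 0.5` extracts a
   stable consensus backbone.
3. **Multiplex features** — cohort skeletons become layers of a multiplex
   network with overall matrix `O` (`o_ij = 1` iff the link exists in at
   least one layer). Per node and layer: strength `s_i = Σ_j w_ij`, inverse
   participation ratio `Y_i = Σ_j (w_ij/s_i)²`, both divided by the overall
   degree `k_i^O`, plus the four degree-conditional means — an `8N × M`
   feature matrix.
4. **Evaluation** — wrapper Random-Forest feature selection (5-fold rounds,
   500 trees, top-quartile permutation importance, stability threshold on
   occurrence), an independent Random Forest for held-out accuracy / AUC /
   sensitivity / specificity, and hub analysis (betweenness outliers beyond
   `Q3 + 1.5·IQR`, hub conservation between dense networks and skeletons,
   Wilcoxon Mann-Whitney group tests).

It is aimed at researchers analysing registered volumetric cohorts (or any
cohort of weighted correlation networks) who want a reduced, interpretable
network representation with a supervised evaluation attached. Synthetic
cohort generators with planted, analytically known group structure make the
whole pipeline testable without any imaging data.

## Worked example

```r
library(salnet)

# a synthetic cohort: 15 + 15 subjects, 120-node networks sharing a
# heavy-tailed backbone, with a planted discriminative star in the cases
cohort <- make_network_cohort(network_cohort_spec(
  n_per_group = 15, n_nodes = 120, seed = 42
))

scan <- threshold_scan(cohort$networks)
glance(scan)
#> # A tibble: 1 × 2
#>   chosen_threshold n_thresholds
#>              <dbl>        <int>
#> 1             0.45           19
```

The scan lands at 0.45 — inside the constructed gap between noise weights
(≤ 0.45) and backbone weights (≥ 0.65), so thresholding recovers the
backbone exactly. Salience then prunes the redundant backbone links:

```r
net <- cohort$networks[[1]]
sfn <- apply_threshold(net, attr(scan, "chosen_threshold"))
S   <- salience_matrix(sfn)
skeleton <- extract_skeleton(S, s_thr = 0.5)
reduction_stats(net, skeleton)
#> # A tibble: 1 × 2
#>   node_reduction link_reduction
#>            <dbl>          <dbl>
#> 1         0.0167          0.665
```

Two thirds of the links vanish while nearly every node keeps at least one
salient edge. Hubs are largely conserved through the reduction:

```r
hub_overlap(detect_hubs(sfn), detect_hubs(skeleton))
#> [1] 0.75
```

The cohort's skeletons feed the multiplex feature matrix, the selection
wrapper, and the classifier:

```r
skeletons <- lapply(cohort$networks, function(n)
  extract_skeleton(salience_matrix(apply_threshold(n, attr(scan, "chosen_threshold")))))
mux <- build_multiplex(skeletons, cohort$networks)
fm  <- feature_matrix(mux, labels = cohort$labels)
fm
#> <feature_matrix> 960 features x 30 subjects (labelled)

sel <- wrapper_select(fm, rounds = 50, seed = 42)
sel
#> <selection_result> 50 of 960 features selected (50 rounds, count >= 45)

train_eval(fm, selected = sel$selected, seed = 42)
#> <classification_report 'group-vs-group'> (50 features, 5-fold x 10 reps)
#>   accuracy     0.963 +/- 0.006
#>   auc          0.997 +/- 0.001
#>   sensitivity  0.987 +/- 0.009
#>   specificity  0.940 +/- 0.007
```

Accuracy 0.96 ± 0.01: the wrapper found the planted nodes (compare
`sel$selected` against `cohort$planted_nodes`) and the held-out forest
separates the groups almost perfectly; with `effect = 0` in the spec the
same pipeline sits at chance. Results carry broom-style `tidy()` /
`glance()` methods and `autoplot()` figures (`autoplot(scan)`,
`autoplot(salience_histogram(S))`).

Volume-based cohorts work the same way through `read_volume()` /
`make_volume_cohort()`, `partition_supervoxels()` and
`build_correlation_network()`; `run_pipeline()` orchestrates every stage
from a JSON config and writes all intermediates plus a run manifest
(`inst/cli/salnet.R` wraps it for shell use).

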