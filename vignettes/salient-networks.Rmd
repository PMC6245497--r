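---
title: "Salient-network skeletons: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salient-network skeletons: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salnet)
```

## The model

`salnet` studies structural brain connectivity as a weighted network per
subject. A registered, intensity-normalized T1 volume is tiled into
fixed-volume rectangular boxes ("supervoxels") of about 3000 mm^3 — the
characteristic size of the anatomical structures affected early in
Alzheimer's disease, such as the hippocampus — and every pair of boxes is
linked by the Pearson correlation of their voxel-intensity vectors. Each
subject therefore contributes a dense, weighted, undirected network whose
nodes are anatomically aligned across subjects.

The analysis then proceeds in three reductions and one evaluation:

1. **Topology threshold.** Edges with correlation at or below a threshold
   `r_thr` are removed. The working threshold is the one at which the two
   canonical brain-network topologies jointly emerge: a scale-free degree
   distribution (diagnosed by the adjusted R^2 of an ordinary least-squares
   fit to the log-log degree histogram) and small-world structure (the ratio
   `(C/C_r)/(L/L_r)` of normalized clustering to normalized path length
   against an Erdos-Renyi reference with the same node count and link
   probability `p = k_bar/N'`).
2. **Salience skeleton.** On the thresholded network, distances are the
   reciprocals of the correlation weights, so highly correlated supervoxels
   are close. For every reference node the shortest-path tree marks each
   edge lying on at least one minimum-distance path to any reachable node;
   an edge's salience is the fraction of the N' trees containing it. The
   salience distribution is strongly bimodal — an edge either belongs to the
   consensus routing structure for almost every vantage point or for almost
   none — so thresholding salience at 0.5 extracts a stable backbone, the
   high-salience skeleton.
3. **Multiplex features.** The skeletons of a cohort are stacked as layers
   of one multiplex network over the shared supervoxel universe, with layer
   weights `|r|` and an overall matrix `O` marking pairs linked in at least
   one layer. Per node and layer the package computes strength, the inverse
   participation ratio `Y_i = sum_j (w_ij/s_i)^2`, both divided by the
   overall degree `k_i^O` (the multiplex-weighted variants), and the four
   degree-conditional means, giving `8N` features per subject.
4. **Evaluation.** A wrapper Random-Forest procedure selects features that
   are stably important across repeated cross-validation rounds, and an
   independent Random Forest reports held-out accuracy, AUC, sensitivity and
   specificity. Hubs — betweenness outliers beyond `Q3 + 1.5 IQR` — are
   compared between dense networks and skeletons and tested between
   clinical groups with the Wilcoxon Mann-Whitney test.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `box_volume_mm3` | 3000 | target supervoxel volume (mm^3); edges chosen as the integer voxel triple nearest the target with max/min edge ratio (in mm) <= 1.2, ties broken lexicographically |
| `r_thr` | chosen by scan | correlation threshold; `threshold_scan()` picks the smallest grid value whose indicator curves sit within 5% of their forward plateau with minimal across-subject variation; a fixed value (e.g. 0.65 for MNI-registered T1 cohorts) can be supplied instead |
| `s_thr` | 0.5 | salience cut; immaterial under bimodality but fixed and inclusive (`>=`) for determinism |
| `trees` | 500 | trees per forest; `mtry = sqrt(f)` |
| `folds`, `rounds` | 5, 1000 | cross-validation structure of the selection wrapper (tests and the acceptance script use `rounds = 100` at desk scale) |
| `pi_thr` | 0.9 | stability threshold of the selection rule (below) |
| `repetitions` | 10 | CV repetitions behind the reported mean and standard error |

## The synthetic cohorts

The package generates both study-shaped inputs without any external data.

**Volume cohorts** share one smooth baseline field (white noise smoothed by a
separable Gaussian kernel, correlation length ~6 mm) plus per-subject voxel
noise. In the case group a per-subject latent pattern is mixed into the
affected boxes as `sqrt(c) z + sqrt(1-c) eps`, which makes the expected
correlation between affected boxes analytic — `c/(1 + sigma^2)` without
baseline — and usable as an oracle.

**Network cohorts** share one preferential-attachment backbone (common
anatomy under registration) with per-subject weights drawn from a band above
a constructed gap, and per-subject noise edges below it, so a correct
threshold scan must land inside the gap. The group-discriminative structure
is a star of planted nodes attached to the backbone by one connector edge.
Two properties of this choice carry the whole planted-recovery test:

* the star is a tree, so its edges have salience exactly 1 and survive
  skeleton extraction, and its leaves are dead ends, so changing their edge
  weights cannot re-route shortest paths anywhere else in the network;
* the case group's weight shift alternates in sign across leaves, so each
  planted edge is individually discriminative while class-wide weight sums —
  and with them the degree-conditional feature means of the large low-degree
  classes — stay unchanged. Signal is thereby confined to features named
  after planted nodes, which is what makes "the selected features name the
  planted nodes" a meaningful recovery criterion.

Default desk-scale conditions: 30 subjects per group, 200 nodes, 20 planted
nodes, backbone weights U(0.65, 0.95), noise weights U(0.15, 0.45), noise
density 0.02, weight shift 0.15. What these cohorts do **not** emulate:
spatial autocorrelation between neighbouring supervoxels, site or scanner
effects, registration error, subject-specific topology differences, and the
power-law weight distribution of real thresholded correlation networks
(backbone weights here live in a narrow band, so cohort skeletons are less
bimodal than brain-derived ones; the bimodality checks therefore use
scale-free graphs with power-law-distributed weights). Passing tests show
the machinery is correct under known structure, not that real MRI cohorts
will reach any particular accuracy.

## Numerical choices

* **Shortest-path ties.** Reciprocal weights make near-ties from rounding
  routine, so an edge `(i,j)` counts as on a shortest path from `n` when
  `|d(n,i) + D_ij - d(n,j)| <= 1e-9 * max(1, d(n,j))` (or symmetrically);
  every tied path is kept, as the salience definition requires.
* **Fragmented networks.** Thresholded graphs routinely fragment. Path
  lengths average over reachable pairs only; the salience denominator stays
  N' (all surviving nodes), so small components dilute their own edges'
  salience — both facts are surfaced as messages.
* **Random-graph references.** `C_r = k_bar/N'` and
  `L_r = ln N' / ln k_bar` are analytic by default, removing sampling noise
  and a seed; `reference = "empirical"` averages 20 sampled graphs instead.
* **Plateau rule.** The scan's plateau test compares each grid point with
  the mean over its forward window (2 grid steps); tail points whose window
  is truncated are not eligible. Among plateau candidates the summed
  coefficient of variation of the two indicators is minimized, smallest
  threshold on ties; if no candidate exists the minimum-variance point is
  used with a warning.
* **Quartiles.** Hub cutoffs and the importance cut both use linear
  interpolation between order statistics (R's type 7) — hub sets depend on
  the convention, so it is fixed.
* **Rank-sum tests.** Exact null for combined n <= 20 without ties;
  otherwise the normal approximation with tie correction.
* **Constant supervoxels.** Zero-variance boxes get zero correlation to
  everything and a warning; the node is kept so indexing stays aligned
  across subjects.
* **Degenerate stages.** Empty thresholded networks and empty skeletons are
  flagged, not raised; empty layers produce all-zero feature columns.

## Design choices where the method was open

* **Selection rule.** The wrapper records, per round, the features above the
  third quartile of the round's fold-averaged permutation importance. With
  p >> n the importance distribution has most of its mass at exactly zero
  and a fixed cohort makes per-round passes of spuriously label-correlated
  features strongly dependent, so a binomial-null count threshold (which
  assumes independent passes) admits the entire stable spurious background —
  its own all-noise calibration fails. The rule used instead is
  stability-selection-style: a feature is selected when it passes in at
  least `pi_thr = 0.9` of rounds. On iid noise this selects under 3% of
  features; on planted cohorts selections concentrate (83-91% across seeds)
  on planted nodes.
* **Multiplex weighting.** The multiplex variants divide the layer quantity
  by the overall degree `k_i^O` — the simplest reading of weighting "on the
  number of links incident upon a node over the whole multiplex network"
  that yields exactly two additional quantities per base measure.
* **Conditional means** group nodes by their layer degree (edge count in the
  layer), since the averaged quantities are per-layer objects. Degree-0
  nodes get 0.
* **Projection freezes O.** A held-out subject's skeleton edges missing from
  the training `O` contribute to its layer features but never enlarge the
  overall degrees; the training multiplex is immutable, and projecting a
  training subject reproduces its training column exactly.
* **Betweenness conventions.** Weighted (reciprocal-distance) betweenness on
  dense/thresholded networks; binary betweenness on skeletons, whose links
  are consensus objects with their weights already consumed. Both are
  overridable.
* **Null evaluation.** Re-evaluating wrapper-selected features on the same
  cohort that selected them measures selection bias, not signal (a
  zero-effect cohort scores ~0.75 that way). Null-calibration checks
  therefore evaluate the full, unselected feature matrix, which sits at
  chance (~0.5). The equivalent remedy on real data is the held-out
  projection path.

## Problem sizes in the tests

The exact-salience oracle enumerates all simple paths, so oracle-equivalence
runs use 50 random connected graphs of 6-12 nodes. Topology calibrations use
20 Erdos-Renyi graphs (N = 200, p = 0.1) and a 100-node ring lattice.
End-to-end planted recovery runs the full default cohort (60 subjects, 200
nodes) with `rounds = 100`; the pipeline unit tests use a 12-subject,
80-node cohort. These sizes are the package's chosen desk-scale study
conditions; the generator defaults, not the tests, define them.

## Known limitations

* Salience is defined for positive weights only; anticorrelations are
  discarded at thresholding, so the method is blind to group effects that
  manifest as negative coupling.
* The salience denominator N' makes skeleton edges of small disconnected
  components unreachable in practice (their salience is bounded by the
  component share), which is the literal definition but worth knowing when
  networks fragment heavily.
* Training-cohort cross-validation after in-cohort feature selection is
  optimistically biased; unbiased estimates need the frozen-multiplex
  projection of genuinely held-out subjects.
* The wrapper at `rounds = 1000`, `trees = 500` is computationally heavy;
  the stability threshold makes shorter runs (`rounds = 100`) behave
  equivalently in the regimes tested here.
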