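---
title: "Bootstrapped metaclustering and arm classification for longitudinal CyTOF studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrapped metaclustering and arm classification for longitudinal CyTOF studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A two-arm randomized study collects whole-blood samples from every patient at
a pre-treatment baseline and at several post-treatment timepoints, and
measures each sample by mass cytometry (CyTOF): tens of thousands of single
cells per sample, each with 26 phenotypic surface markers (cell identity) and
11 intracellular functional markers (signaling state). The scientific
questions are (i) *whether* the two arms' immune systems diverge at each
timepoint, (ii) *where* in the immune system the divergence occurs, and
(iii) *how* each patient's immune state moves through time along innate and
adaptive directions.

cytoboot implements a complete pipeline for these questions:

1. **Bootstrapped metaclustering** — every sample is clustered independently
   by k-means into `round(sqrt(N/2))` coarse clusters on the phenotypic
   markers (N = cells in the sample), so no cell is ever downsampled; the
   pooled sample-cluster centers are then clustered into K metaclusters, and
   this metaclustering is repeated B times with fresh random initializations
   to absorb k-means run-to-run variability. Defaults: K = 30, B = 200.
2. **Cluster features** — for every sample and every (iteration,
   metacluster): its *frequency* (percent of the sample's total events,
   including any excluded neutrophils) and, per functional marker, its
   *signaling response*: the median arcsinh intensity minus the same
   patient's baseline-sample median in the iteration-matched cluster. The
   field calls this difference an "arcsinh ratio"; it is a difference of
   arcsinh-scale medians, never a quotient.
3. **Per-timepoint classification** — a repeated leave-group-out
   random-forest ensemble: at each of `n_iter` iterations a stratified random
   half of the patients trains a forest and the held-out half is scored with
   the predicted treated-arm probability; a sample's score is the median of
   its held-out predictions. The scores give the ROC/AUC (equivalently the
   Mann-Whitney statistic) and a two-sided Wilcoxon rank-sum p-value for arm
   separation.
4. **Immune-cell atlas** — each (iteration, metacluster) is summarized by the
   median of its pooled cells' phenotypic markers; PCA of this clusters ×
   markers matrix gives 2-D coordinates on which per-cluster two-group
   statistics are painted: the best univariate −log10 p over a cluster's
   features, and signed maps `sign(r) · (−log10 p)` where sign(r) is +1/−1
   when the feature mean is higher/lower in the treated arm (0 on exact
   ties).
5. **Immune trajectories** — per-sample gated-population feature vectors
   (frequencies + basal signaling medians), baseline-subtracted so every
   patient starts at the origin, are split into innate and adaptive feature
   groups and embedded separately with one-dimensional Isomap, giving the
   innate X and adaptive Y axes of the trajectory plots. A least-squares
   linear extension of each embedding provides continuous interpolation
   between observed timepoints (for animation).

# The synthetic-study generator

No public per-cell generative model accompanies the study design this
package targets (it is a randomized trial), so all distributional choices in
`generate_study()` are explicit stand-ins, chosen once as plausible for
arcsinh-transformed CyTOF data:

* **Populations.** Twelve populations (neutrophils; classical,
  non-classical monocytes; mDC; pDC; NK; naive/memory CD4 T; CD8 T; Treg; B;
  γδ T) with canonical surface signatures: background ≈ 0.3 and lineage
  markers ≈ 3-4 arcsinh units, per-marker spread 0.4. Marker values are
  independent Gaussians per population on the arcsinh scale — the simplest
  model with the statistical structure the pipeline assumes (unimodal,
  roughly homoskedastic populations). Zero-inflation, marker correlation,
  doublets, spillover and acquisition drift are deliberately not modeled;
  passing tests therefore demonstrate correctness of the pipeline's
  statistics, not robustness to those real-data artifacts.
* **Counts.** Per-sample population counts are multinomial over the
  (effect-adjusted, renormalized) base fractions; cell counts per sample are
  fixed or drawn uniformly from a range, which exercises the `sqrt(N/2)`
  rule at different N.
* **Baseline neutrality.** Arm labels influence nothing at baseline.
  Post-baseline, a *surgery response* (an additive time profile on
  functional-marker means, peaking at 1-24 h and resolved by 2 weeks)
  applies to **both** arms; planted `effect_spec()`s apply only to their
  target arm, populations and timepoints, as a frequency multiplier and/or
  additive signaling shifts.
* **Patient intercepts.** Each patient carries a Gaussian random intercept
  (sd 0.1 arcsinh units) on all functional-marker means, constant over time,
  giving baseline subtraction something real to remove.
* **Determinism.** Every sample's cells are drawn under a seed derived from
  the master seed and the (patient, timepoint) identity, so studies are
  byte-identical across runs and platforms and independent of evaluation
  order.

The default design mirrors a two-arm trial with 30 control and 28 treated
patients and six timepoints (baseline, 1 h, 6 h, 24 h, 48 h, 2 wk); the
default of 5000 cells per sample keeps a full default study tractable on a
laptop while leaving per-population medians precise to a few hundredths of
an arcsinh unit.

# Numerical and design choices

* **Arcsinh cofactor** defaults to 5 — the mass-cytometry convention; the
  transform is `asinh(x / cofactor)`. `cell_table`s carry a scale flag and
  refuse a second transform, because silent double-transformation is a
  classic cytometry bug.
* **k-means.** Cluster counts use round-half-away-from-zero with a floor of
  one (`kmeans_k_rule()`). Fits use k-means++ seeding (authored in-package,
  since no installed dependency exposes it) feeding `stats::kmeans`
  (Hartigan-Wong), 10 restarts, best total within-cluster sum of squares;
  Euclidean distance in arcsinh space. Metaclustering operates on unweighted
  centers — each sample-cluster center is one point regardless of how many
  cells it summarizes. When a sample has fewer distinct points than k, k is
  reduced with a warning; when the pooled centers hold fewer distinct points
  than K, the error instructs a smaller K.
* **Neutrophils** (by ground-truth compartment label) are excluded from
  clustering by default and analyzed separately, but remain in the
  frequency denominator: cluster frequencies are percentages of the
  sample's *total* events.
* **Missingness.** A population or cluster empty in a sample yields missing
  medians, propagated as missing — never imputed as zero. The classifier
  imputes missing features with the *training-half* median inside each CV
  iteration, so no test information leaks into training; columns missing
  everywhere are dropped with a warning.
* **Classifier.** Random forests use 500 trees (200 in the reduced demo),
  `mtry = floor(sqrt(p))`, fully grown trees (`min.node.size = 1` — the
  probability-forest default of 10 would forbid any split at the small
  training sizes this design produces), and a derived seed per iteration.
  The split unit is the patient, halves are stratified by arm, and
  iterations are topped up until every sample has been held out at least
  once (a drop mode is available). The baseline timepoint runs through the
  identical machinery with frequency + basal features, since baseline
  samples have no baseline-subtracted responses.
* **Wilcoxon rank-sum.** Exact enumeration when the pooled size is ≤ 20
  with no ties, else the normal approximation with tie and continuity
  correction (delegated to `stats::wilcox.test`; fully tied input returns
  p = 1). AUC is computed as the Mann-Whitney pairwise probability with
  ties counted half.
* **Atlas.** PCA is fitted on cluster cell-level medians (a centroid mode is
  available), centered but not scaled — all phenotypic markers share arcsinh
  units, so per-marker scaling would only amplify uninformative markers. Raw
  best p-values are displayed, matching the method's descriptive intent; a
  Benjamini-Hochberg layer is available but off by default. sign(r) ties
  give 0.
* **Isomap.** `n_neighbors` defaults to 10; the neighborhood graph is
  checked for connectivity up front and a disconnected graph is an error
  naming component sizes. Eigen-embeddings are sign-ambiguous, so each axis
  is oriented by convention: the group-median coordinate at the first
  post-baseline timepoint is made ≥ the baseline median. The "linear
  transformation" used for continuous trajectory animation is implemented
  as a least-squares affine extension of the embedding (interpretation:
  interpolation between snapshots, not out-of-sample embedding); a
  rank-deficient feature matrix falls back to a lightly ridge-regularized
  fit with a warning.
* **Trajectory features** are the gated-population frequencies (percent)
  and basal signaling medians (arcsinh units) in their native units, as the
  method prescribes only baseline subtraction. Because percent-scale
  frequency noise and arcsinh-scale signaling then share one Euclidean
  metric, planted signaling-only perturbations compete with frequency
  sampling noise; the validation suite's adaptive-compartment perturbation
  therefore combines STAT-pathway shifts with a naive→memory CD4 T
  redistribution that leaves the total adaptive fraction (and hence every
  innate frequency) unchanged.

# Validation design and problem sizes

The package validates itself entirely on synthetic studies; all suite sizes
were chosen once, as reduced but statistically meaningful stand-ins for the
full design:

* Exact oracles: AUC against brute-force pair counting (up to 50 per arm);
  rank-sum p against exhaustive rank-assignment enumeration (all group
  sizes up to 8 + 8); arcsinh against its closed form.
* Null behavior: 50 studies of 12 vs 12 patients, 1000 cells/sample,
  baseline + 6 h, B = 20, K = 10, 50 classifier iterations.
* Effect recovery: 20 studies of 10 vs 10 patients, 2000 cells/sample,
  planting a halved CD4 memory T frequency plus a +1.0 arcsinh pSTAT3
  response shift post-baseline; the same studies drive the atlas
  localization and sign checks.
* Trajectories: the adaptive-only perturbation above (8 vs 8 patients,
  800 cells/sample), plus noiseless 1-D manifold recovery checks for
  Isomap.

A note on small-cohort null behavior: with 24 patients and thousands of
cluster features, the maximum chance single-feature separation between arms
is large (best-of-many selection at n = 24), and the leave-group-out
ensemble rediscovers such chance features in every split half. The null
distribution of the ensemble AUC at this cohort size is therefore visibly
heavier-tailed than the Mann-Whitney null of an independent score — a
property of the method at small n, discussed with measurements in the
package's validation results rather than hidden by recalibration.

# Known limitations

* CSV (plus manifest + panel YAML) is the interchange format; binary FCS
  reading is not provided.
* The generator's independence assumptions (across markers and cells) make
  clustering easier than on real data; metacluster counts K well below the
  true population count will merge populations silently.
* Wilcoxon p-values on ensemble probabilities inherit the dependence of
  shared training sets; they are descriptive, as in the method being
  implemented, not calibrated tests.
* One Isomap component per compartment is hard-wired into the trajectory
  view; richer structure needs the atlas instead.
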