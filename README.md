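# cytoboot

Bootstrapped metaclustering, leave-group-out classification, and
trajectory embedding for two-arm longitudinal mass-cytometry (CyTOF)
studies.

## The problem

A randomized two-arm study samples every patient's blood at a pre-treatment
baseline and at several post-treatment timepoints; each sample yields
thousands of single cells with 26 phenotypic and 11 functional (phospho-)
markers. cytoboot answers three questions about such a study:

* **Whether** the arms differ at a timepoint — a repeated leave-group-out
  random-forest ensemble over cluster-derived features; per-sample scores
  are median held-out treated-arm probabilities, summarized by the ROC AUC
  (the Mann-Whitney statistic) and a two-sided Wilcoxon rank-sum p-value.
* **Where** they differ — a downsampling-free bootstrapped metaclustering:
  per-sample k-means with k = √(N/2) on phenotypic markers, then the pooled
  sample-cluster centers are k-means-clustered into K = 30 metaclusters,
  repeated B = 200 times. Every (iteration, metacluster) gets a frequency
  feature (percent of the sample's total events) and per-marker signaling
  responses (median arcsinh intensity minus the patient's baseline median —
  the "arcsinh ratio", a difference, not a quotient). Per-cluster two-group
  statistics (best −log₁₀ p and sign(r)·−log₁₀ p) are painted on a 2-D PCA
  "immune atlas" of cluster marker medians.
* **How** each patient's immune state moves — gated-population feature
  vectors, baseline-subtracted, split into innate and adaptive groups and
  embedded with one-dimensional Isomap each: the innate X and adaptive Y
  trajectory axes.

A synthetic-study generator with known population structure and plantable
arm effects makes the whole pipeline testable without any data download.

## A worked example

```r
library(cytoboot)

## a reduced planted-effect study: 10 vs 10 patients, baseline + 6 h,
## 1000 cells/sample; the treatment arm halves CD4 memory T-cell frequency
## and shifts its pSTAT3 response by +1 arcsinh unit at 6 h
res <- run_demo(out_dir = "demo_out", seed = 3)

res$classifiers[["baseline"]]
#> classifier_result @ baseline: AUC = 0.295, p = 0.13 (50 LOGO iterations, treated arm 'treatment')
res$classifiers[["6h"]]
#> classifier_result @ 6h: AUC = 1.000, p = 0.000181 (50 LOGO iterations, treated arm 'treatment')
```

The classifier separates the arms perfectly at 6 h (AUC = 1.0, rank-sum
p ≈ 2 × 10⁻⁴, the resolution limit of 10 + 10 samples) while the baseline —
where no effect exists — stays near chance (small-cohort null AUCs scatter
widely around 0.5; see the methods vignette). The atlas pinpoints the
perturbed cells:

```r
comp <- cluster_composition(res$study, res$clustering)
enr  <- population_enrichment(comp, res$atlas_stats[["6h"]], "CD4Tmem")
enr$p_value        # Fisher enrichment of CD4Tmem in the top-decile clusters
#> ~1e-300 (reported as 0): the most significant clusters are CD4 memory T cells
```

`demo_out/` contains the per-sample CSVs and manifest, the cluster feature
matrix, classifier JSONs, atlas statistics and PNGs, trajectory coordinates,
a run log, and an MD5 manifest; re-running with the same seed reproduces the
deterministic artifact hashes bit-for-bit.

Individual stages are plain functions: `generate_study()`,
`cluster_study()`, `build_cluster_features()`, `classify_timepoint()`,
`atlas_coordinates()` / `cluster_group_stats()` / `plot_atlas()`,
`trajectory_embedding()` / `plot_trajectories()`. A thin command-line
wrapper lives at `inst/scripts/cytoboot.R`.

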