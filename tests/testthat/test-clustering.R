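test_that("the sqrt(N/2) rule rounds half away from zero with floor 1", {
  expect_equal(kmeans_k_rule(5000), 50)
  expect_equal(kmeans_k_rule(2), 1)
  expect_equal(kmeans_k_rule(1), 1)
  expect_equal(kmeans_k_rule(12), 2)   # sqrt(6)  = 2.449 -> 2
  expect_equal(kmeans_k_rule(13), 3)   # sqrt(6.5) = 2.550 -> 3
  expect_equal(kmeans_k_rule(c(5000, 200)), c(50, 10))
})

test_that("per-sample k-means labels every cell and respects separation", {
  set.seed(1)
  masses <- rbind(matrix(rnorm(100 * 5, 0), ncol = 5),
                  matrix(rnorm(100 * 5, 12), ncol = 5),
                  matrix(rnorm(100 * 5, -12), ncol = 5))
  truth <- rep(1:3, each = 100)
  fit <- cluster_sample(masses, k_rule = function(N) 12L, seed = 7)
  expect_equal(length(fit$labels), 300)
  expect_equal(fit$k, 12)
  ## every center must lie inside exactly one mass, never straddle two
  mass_centers <- rbind(rep(0, 5), rep(12, 5), rep(-12, 5))
  d <- as.matrix(dist(rbind(fit$centers, mass_centers)))[1:12, 13:15]
  nearest <- apply(d, 1, min)
  expect_true(all(nearest < 6))
  ## and cells in one k-means cluster all come from the same mass
  expect_true(all(vapply(split(truth, fit$labels),
                         function(v) length(unique(v)), numeric(1)) == 1))
})

test_that("k is reduced with a warning when N < k", {
  x <- matrix(rnorm(10), 2, 5)
  expect_warning(fit <- cluster_sample(x, k_rule = function(N) 5L, seed = 1),
                 "reduced")
  expect_equal(fit$k, 2)
  expect_equal(sort(unique(fit$labels)), 1:2)
})

test_that("cluster_sample is deterministic given its seed", {
  x <- matrix(rnorm(500 * 4), 500, 4)
  f1 <- cluster_sample(x, seed = 99)
  f2 <- cluster_sample(x, seed = 99)
  expect_identical(f1, f2)
})

test_that("metaclustering is deterministic and sized B x K", {
  st <- generate_study(tiny_config(n_per_arm = 2, cells = 300, seed = 18))
  cfg <- cluster_config(K = 4, B = 3, seed = 5)
  cl1 <- cluster_study(st, cfg)
  cl2 <- cluster_study(st, cfg)
  expect_identical(cl1$models, cl2$models)
  expect_equal(length(cl1$models), 3)
  for (mdl in cl1$models) {
    expect_equal(dim(mdl$centroids), c(4, 4))  # K x P(phenotypic)
    expect_true(all(is.finite(mdl$centroids)))
    expect_true(all(mdl$assignment %in% 1:4))
    expect_equal(length(mdl$assignment), nrow(cl1$centers))
  }
})

test_that("printed defaults give 6000 cluster-feature groups", {
  cfg <- cluster_config()
  expect_equal(cfg$K * cfg$B, 6000)
})

test_that("three separated populations are recovered exactly at K = 3", {
  skip_if_not_installed("mclust")
  st <- generate_study(tiny_config(n_per_arm = 2, cells = 400, seed = 23))
  cl <- cluster_study(st, cluster_config(K = 3, B = 2, seed = 2))
  for (b in 1:2) {
    for (sid in st$metadata$sample_id[1:4]) {
      mc <- assign_cells(cl, sid, b)
      truth <- st$samples[[sid]]$population_labels
      expect_equal(mclust::adjustedRandIndex(mc, truth), 1.0)
    }
  }
})

test_that("cell assignment maps through sample clusters, no cell-level distances", {
  st <- generate_study(tiny_config(n_per_arm = 2, cells = 200, seed = 25))
  cl <- cluster_study(st, cluster_config(K = 3, B = 2, seed = 3))
  sid <- st$metadata$sample_id[1]
  mc <- assign_cells(cl, sid, 1)
  sc <- cl$sample_clusters[[sid]]
  rows <- which(cl$provenance$sample_id == sid)
  map <- cl$models[[1]]$assignment[rows]
  expect_identical(mc, map[sc$labels])
  expect_error(assign_cells(cl, "no_such_sample", 1), class = "cytoboot_consistency_error")
  expect_error(assign_cells(cl, sid, 99), class = "cytoboot_consistency_error")
})

test_that("every non-excluded cell is clustered (downsampling-free audit)", {
  st <- generate_study(tiny_config(n_per_arm = 2, cells = 250, seed = 26,
                                   with_neutrophils = TRUE))
  cl <- cluster_study(st, cluster_config(K = 3, B = 1, seed = 4))
  for (sid in st$metadata$sample_id) {
    ct <- st$samples[[sid]]
    n_neut <- sum(ct$population_labels == "Neutrophil")
    sc <- cl$sample_clusters[[sid]]
    expect_equal(sc$n_clustered, nrow(ct$values) - n_neut)
    expect_equal(sum(!is.na(sc$labels)), sc$n_clustered)
    expect_equal(sum(table(sc$labels[!is.na(sc$labels)])), sc$n_clustered)
  }
})

test_that("cluster frequencies use total events as denominator", {
  ## hand-built: 1000 clustered cells in groups 600/250/150 plus 200
  ## excluded neutrophils -> 50%, 20.83%, 12.5% of the 1200 events
  st <- manual_study(c(Tcell = 600, Mono = 250, Bcell = 150, Neutrophil = 200),
                     values_by_pop = list(Tcell = 0, Mono = 2, Bcell = 4, Neutrophil = 6))
  cl <- suppressWarnings(cluster_study(st, cluster_config(K = 3, B = 1, seed = 6)))
  fe <- build_cluster_features(st, cl)
  freq_cols <- fe$columns$column[fe$columns$feature_type == "frequency"]
  freqs <- sort(as.numeric(fe$values[1, freq_cols]), decreasing = TRUE)
  expect_equal(freqs, c(600, 250, 150) / 1200 * 100)
  expect_lt(abs(sum(freqs) - 100 * 1000 / 1200), 1e-9)
})

test_that("frequency columns sum to 100 x clustered / total per iteration", {
  st <- generate_study(tiny_config(n_per_arm = 2, cells = 300, seed = 27,
                                   with_neutrophils = TRUE))
  cl <- cluster_study(st, cluster_config(K = 3, B = 2, seed = 7))
  fe <- build_cluster_features(st, cl)
  for (sid in st$metadata$sample_id) {
    sc <- cl$sample_clusters[[sid]]
    for (b in 1:2) {
      cols <- fe$columns$column[fe$columns$feature_type == "frequency" &
                                  fe$columns$iteration == b]
      expect_lt(abs(sum(fe$values[sid, cols]) - 100 * sc$n_clustered / sc$n_total), 1e-9)
    }
  }
})

test_that("responses vanish when a post sample duplicates its baseline", {
  st <- generate_study(tiny_config(n_per_arm = 2, cells = 150, seed = 28))
  bl <- st$samples[["control_01_baseline"]]
  post <- st$samples[["control_01_6h"]]
  post$values <- bl$values
  post$population_labels <- bl$population_labels
  st$samples[["control_01_6h"]] <- post
  cl <- cluster_study(st, cluster_config(K = 3, B = 2, seed = 8))
  fe <- build_cluster_features(st, cl)
  resp_cols <- fe$columns$column[fe$columns$feature_type == "response"]
  v <- fe$values["control_01_6h", resp_cols]
  expect_true(all(abs(v[!is.na(v)]) < 1e-12))
  freq_cols <- fe$columns$column[fe$columns$feature_type == "frequency"]
  expect_equal(as.numeric(fe$values["control_01_6h", freq_cols]),
               as.numeric(fe$values["control_01_baseline", freq_cols]))
})

test_that("too few distinct centers for K is an instructive error", {
  st <- manual_study(c(Tcell = 20, Mono = 10, Bcell = 10),
                     values_by_pop = list(Tcell = 0, Mono = 2, Bcell = 4))
  expect_error(suppressWarnings(cluster_study(st, cluster_config(K = 10, B = 1, seed = 1))),
               "smaller K", class = "cytoboot_config_error")
})
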