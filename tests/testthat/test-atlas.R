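## Fake clustering whose metacluster cell medians we control exactly: each
## population is one sample cluster, mapped to its own metacluster.
identity_clustering <- function(st, K) {
  sids <- st$metadata$sample_id
  pops <- st$populations$population
  sample_clusters <- list()
  prov <- list()
  for (sid in sids) {
    lab <- match(st$samples[[sid]]$population_labels, pops)
    sample_clusters[[sid]] <- list(
      centers = matrix(0, K, sum(st$panel$role == "phenotypic"),
                       dimnames = list(NULL, st$panel$marker[st$panel$role == "phenotypic"])),
      labels = lab, k = K, n_total = length(lab), n_clustered = length(lab))
    prov[[sid]] <- data.frame(sample_id = sid, cluster = seq_len(K))
  }
  structure(list(config = cluster_config(K = K, B = 1, seed = 1),
                 sample_clusters = sample_clusters,
                 centers = do.call(rbind, lapply(sample_clusters, `[[`, "centers")),
                 provenance = do.call(rbind, prov),
                 models = list(list(iteration = 1L,
                                    centroids = sample_clusters[[1]]$centers,
                                    assignment = rep(seq_len(K), length(sids))))),
            class = "cytoboot_clustering")
}

test_that("clusters with identical cells get identical atlas coordinates", {
  st <- manual_study(c(Tcell = 40, Mono = 40, Bcell = 40),
                     values_by_pop = list(Tcell = 1, Mono = 1, Bcell = 3))
  cl <- identity_clustering(st, K = 3)
  at <- atlas_coordinates(st, cl)
  expect_equal(at$coords[1, c("PC1", "PC2")], at$coords[2, c("PC1", "PC2")],
               ignore_attr = TRUE)
  expect_gte(var(at$coords$PC1), var(at$coords$PC2))
})

test_that("a rank-2 median matrix is reproduced exactly by two components", {
  ## constant cells per population whose phenotype vectors span a 2-D plane
  panel <- tiny_panel()
  ph <- panel$marker[panel$role == "phenotypic"]
  u <- c(1, 0, 2, -1); v <- c(0, 2, 1, 1)
  mk <- function(a, b) stats::setNames(3 + a * u + b * v, ph)
  vals <- list(Tcell = c(mk(1, 0), pSTAT3 = 0, pCREB = 0),
               Mono = c(mk(0, 1), pSTAT3 = 0, pCREB = 0),
               Bcell = c(mk(2, 1), pSTAT3 = 0, pCREB = 0),
               Extra = c(mk(-1, 2), pSTAT3 = 0, pCREB = 0))
  st <- manual_study(c(Tcell = 30, Mono = 30, Bcell = 30, Extra = 30),
                     values_by_pop = lapply(vals, function(x) x[panel$marker]))
  cl <- identity_clustering(st, K = 4)
  at <- atlas_coordinates(st, cl)
  rec <- cbind(at$coords$PC1, at$coords$PC2) %*% t(at$pca$rotation[, 1:2])
  rec <- sweep(rec, 2, at$pca$center, `+`)
  expect_lt(max(abs(rec - at$medians)), 1e-9)
})

test_that("separated populations form separated atlas blobs", {
  st <- generate_study(tiny_config(n_per_arm = 3, cells = 400, seed = 33))
  cl <- cluster_study(st, cluster_config(K = 3, B = 10, seed = 3))
  at <- atlas_coordinates(st, cl)
  comp <- cluster_composition(st, cl)
  dom <- stats::aggregate(n_cells ~ iteration + metacluster, comp, max)
  dom$population <- comp$population[match(
    paste(dom$iteration, dom$metacluster, dom$n_cells),
    paste(comp$iteration, comp$metacluster, comp$n_cells))]
  df <- merge(at$coords, dom[, c("iteration", "metacluster", "population")])
  cent <- stats::aggregate(df[, c("PC1", "PC2")], by = list(pop = df$population), mean)
  within <- max(vapply(split(df, df$population), function(g) {
    stats::quantile(sqrt((g$PC1 - mean(g$PC1))^2 + (g$PC2 - mean(g$PC2))^2), 0.95)
  }, numeric(1)))
  between <- min(dist(cent[, c("PC1", "PC2")]))
  expect_gt(between, within)
})

test_that("fewer than three clusters cannot be mapped", {
  st <- manual_study(c(Tcell = 30, Mono = 30))
  cl <- identity_clustering(st, K = 2)
  cl$config <- cluster_config(K = 2, B = 1, seed = 1)
  expect_error(atlas_coordinates(st, cl), class = "cytoboot_state_error")
})

test_that("group statistics follow the sign(r) convention", {
  set.seed(9)
  n <- 6
  arm <- rep(c("control", "treatment"), each = n)
  meta <- data.frame(sample_id = sprintf("s%02d", 1:(2 * n)),
                     patient_id = sprintf("p%02d", 1:(2 * n)),
                     arm = arm, timepoint = "6h", stringsAsFactors = FALSE)
  ## col 1: higher in treatment; col 2: higher in control; col 3: null
  X <- cbind(c(1:n, (1:n) + 10), c((1:n) + 10, 1:n), rnorm(2 * n))
  colnames(X) <- c("up", "down", "null")
  rownames(X) <- meta$sample_id
  fe <- manual_features(X, meta)
  gs <- cluster_group_stats(fe, "6h")
  s <- gs$stats
  expect_equal(s$sign_r[1], 1)
  expect_equal(s$sign_r[2], -1)
  expect_equal(s$signed_logp[1], -log10(s$p[1]))
  expect_equal(s$signed_logp[2], log10(s$p[2]))
  ## best_logp is the per-cluster max of -log10 p
  expect_equal(gs$best$best_logp[gs$best$metacluster == 1], -log10(s$p[1]))
  ## exact tie in means gives sign 0
  X2 <- X; X2[, "up"] <- rep(c(1, 2, 3), length.out = 2 * n)
  gs2 <- cluster_group_stats(manual_features(X2, meta), "6h")
  expect_equal(gs2$stats$sign_r[1], 0)
})

test_that("features missing in over half an arm are excluded with a warning", {
  fe <- make_logo_fixture(seed = 12)
  fe$values[1:8, "f2"] <- NA  # 8 of 10 control samples missing
  expect_warning(gs <- cluster_group_stats(fe, "6h"), "excluded")
  expect_true(is.na(gs$stats$p[gs$stats$metacluster == 2]))
})

test_that("atlas rendering writes files and rejects unknown modes", {
  st <- generate_study(tiny_config(n_per_arm = 3, cells = 200, seed = 35))
  cl <- cluster_study(st, cluster_config(K = 3, B = 2, seed = 5))
  at <- atlas_coordinates(st, cl)
  fe <- build_cluster_features(st, cl)
  gs <- cluster_group_stats(fe, "6h")
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "best.png")
  f2 <- file.path(dir, "signed.png")
  f3 <- file.path(dir, "pheno.png")
  plot_atlas(at, gs, mode = "best_p", file = f1)
  plot_atlas(at, gs, mode = "signed", marker = "pSTAT3", file = f2)
  plot_atlas(at, mode = "phenotype", marker = "CD3", file = f3)
  expect_true(all(file.exists(f1, f2, f3)))
  expect_error(plot_atlas(at, gs, mode = "rainbow"), class = "cytoboot_parameter_error")
  expect_error(plot_atlas(at, mode = "phenotype"), class = "cytoboot_parameter_error")
})

test_that("statistics are invariant to rotations of the atlas coordinates", {
  ## the coloring statistics never read the coordinates; verify stats are a
  ## function of features alone by recomputing after rotating coordinates
  st <- generate_study(tiny_config(n_per_arm = 3, cells = 200, seed = 36))
  cl <- cluster_study(st, cluster_config(K = 3, B = 2, seed = 6))
  fe <- build_cluster_features(st, cl)
  gs1 <- cluster_group_stats(fe, "6h")
  gs2 <- cluster_group_stats(fe, "6h")
  expect_identical(gs1$stats, gs2$stats)
})
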