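test_that("baseline normalization zeroes baselines and is idempotent", {
  st <- generate_study(tiny_config(n_per_arm = 3, cells = 200, seed = 41))
  x <- sample_feature_vectors(st)
  xn <- baseline_normalize(x, st)
  bl_rows <- st$metadata$sample_id[st$metadata$timepoint == "baseline"]
  expect_true(all(abs(xn[bl_rows, ]) < 1e-12))
  expect_equal(unname(baseline_normalize(xn, st)), unname(xn))
  ## post sample duplicated from baseline normalizes to zero too
  x2 <- x
  x2["control_01_6h", ] <- x["control_01_baseline", ]
  xn2 <- baseline_normalize(x2, st)
  expect_true(all(abs(xn2["control_01_6h", ]) < 1e-12))
})

test_that("patients without baseline are excluded from trajectories", {
  st <- generate_study(tiny_config(n_per_arm = 3, cells = 150, seed = 42))
  x <- sample_feature_vectors(st)
  x <- x[rownames(x) != "control_01_baseline", ]
  expect_warning(xn <- baseline_normalize(x, st), "control_01")
  expect_false("control_01_6h" %in% rownames(xn))
})

test_that("Isomap preserves the ordering of points along a line", {
  set.seed(5)
  t_par <- sort(runif(100))
  dir10 <- rnorm(10)
  x <- outer(t_par, dir10)
  emb <- isomap_embed(x, n_neighbors = 10)[, 1]
  expect_equal(abs(cor(emb, t_par, method = "spearman")), 1.0)
})

test_that("Isomap recovers arc-length order on a noiseless quarter circle", {
  theta <- seq(0, pi / 2, length.out = 100)
  x <- cbind(cos(theta), sin(theta))
  emb <- isomap_embed(x, n_neighbors = 8)[, 1]
  expect_gte(abs(cor(emb, theta, method = "spearman")), 0.99)
})

test_that("duplicated points receive identical Isomap coordinates", {
  set.seed(6)
  x <- matrix(rnorm(30 * 3), 30, 3)
  x[30, ] <- x[1, ]
  emb <- isomap_embed(x, n_neighbors = 5)[, 1]
  expect_lt(abs(emb[30] - emb[1]), 1e-8)
})

test_that("a disconnected neighborhood graph is an error naming components", {
  x <- rbind(matrix(rnorm(24 * 3, 0, 0.1), 24, 3),
             matrix(rnorm(12 * 3, 100, 0.1), 12, 3))
  expect_error(isomap_embed(x, n_neighbors = 4), "24",
               class = "cytoboot_state_error")
  expect_error(isomap_embed(matrix(rnorm(10), 5, 2), n_neighbors = 10),
               class = "cytoboot_parameter_error")
})

test_that("the linear extension is exact on a linear manifold and affine", {
  set.seed(7)
  t_par <- sort(runif(60))
  x <- outer(t_par, rnorm(6)) + matrix(rnorm(60 * 6, 0, 1e-8), 60)
  emb <- isomap_embed(x, n_neighbors = 8)[, 1]
  map <- suppressWarnings(linear_extension(x, emb))
  pred <- predict(map, x)
  expect_gt(abs(cor(pred, emb)), 0.999)
  a <- x[10, ]; b <- x[40, ]
  for (al in c(0, 0.3, 1)) {
    expect_lt(abs(predict(map, al * a + (1 - al) * b) -
                    (al * predict(map, a) + (1 - al) * predict(map, b))), 1e-8)
  }
  expect_equal(predict(map, a), pred[10])
  ## rank-deficient features fall back to ridge with a warning
  xr <- cbind(x, x[, 1])
  expect_warning(linear_extension(xr, emb), "rank deficient")
})

test_that("an adaptive-only effect separates arms mostly along the adaptive axis", {
  ## a naive -> memory CD4 T redistribution plus STAT shifts: confined to the
  ## adaptive compartment (total adaptive fraction is unchanged, so innate
  ## frequencies are untouched by renormalization)
  st <- generate_study(adaptive_effect_config(seed = 44))
  emb <- suppressWarnings(trajectory_embedding(st, n_neighbors = 8))
  co <- emb$coords[emb$coords$timepoint == "6h", ]
  med <- function(v, a) median(v[co$arm == a])
  dy <- abs(med(co$y_adaptive, "treatment") - med(co$y_adaptive, "control"))
  dx <- abs(med(co$x_innate, "treatment") - med(co$x_innate, "control"))
  expect_gte(dy, 3 * dx)
})

test_that("axis orientation puts the first post-baseline median above baseline", {
  st <- generate_study(study_config(n_patients_per_arm = 6,
                                    timepoints = c("baseline", "6h"),
                                    cells_per_sample = 500, seed = 45))
  emb <- suppressWarnings(trajectory_embedding(st, n_neighbors = 6))
  co <- emb$coords
  for (ax in c("x_innate", "y_adaptive")) {
    expect_gte(median(co[[ax]][co$timepoint == "6h"]),
               median(co[[ax]][co$timepoint == "baseline"]))
  }
})

test_that("the embedding is stable under dropping one patient", {
  st <- generate_study(study_config(n_patients_per_arm = 8,
                                    timepoints = c("baseline", "6h"),
                                    cells_per_sample = 500, seed = 46))
  x <- sample_feature_vectors(st)
  xn <- baseline_normalize(x, st)
  comp <- attr(xn, "compartment")
  adaptive <- xn[, comp == "adaptive", drop = FALSE]
  full <- isomap_embed(adaptive, n_neighbors = 6)[, 1]
  drop <- !grepl("^control_01_", rownames(adaptive))
  sub <- isomap_embed(adaptive[drop, , drop = FALSE], n_neighbors = 6)[, 1]
  rho <- abs(cor(full[drop], sub, method = "spearman"))
  expect_gt(rho, 0.9)
})
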