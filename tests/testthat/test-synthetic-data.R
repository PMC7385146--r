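test_that("generated study has the configured dimensions and labels", {
  cfg <- study_config(n_patients_per_arm = 3, timepoints = c("baseline", "6h"),
                      cells_per_sample = 1000, seed = 11)
  st <- generate_study(cfg)
  expect_equal(nrow(st$metadata), 12)  # 2 arms x 3 patients x 2 timepoints
  expect_setequal(unique(st$metadata$arm), c("control", "treatment"))
  for (ct in st$samples) {
    expect_equal(dim(ct$values), c(1000, 37))
    expect_equal(length(ct$population_labels), 1000)
    expect_true(all(ct$population_labels %in% st$populations$population))
  }
})

test_that("same seed reproduces a bit-identical study; different seed differs", {
  cfg <- tiny_config(seed = 5)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_identical(st1, st2)
  st3 <- generate_study(tiny_config(seed = 6))
  expect_false(identical(st1$samples[[1]]$values, st3$samples[[1]]$values))
})

test_that("cells_per_sample ranges are respected and counts conserved", {
  cfg <- tiny_config(cells = c(200, 400), seed = 8)
  st <- generate_study(cfg)
  ns <- vapply(st$samples, nrow, numeric(1))
  expect_true(all(ns >= 200 & ns <= 400))
  for (ct in st$samples) {
    expect_equal(sum(table(ct$population_labels)), nrow(ct$values))
  }
})

test_that("a planted signaling shift is recovered at cell level", {
  ## +1.0 arcsinh units on pSTAT3 in CD4Tmem, treatment arm, 6 h; pooled
  ## cell counts are large enough that the empirical arm difference must sit
  ## within 3 standard errors of the planted value.
  cfg <- study_config(
    n_patients_per_arm = 6, timepoints = c("baseline", "6h"),
    cells_per_sample = 6000, patient_effect_sd = 0,
    effects = list(effect_spec("CD4Tmem", "treatment", "6h",
                               signaling_shift = c(pSTAT3 = 1.0))),
    seed = 21)
  st <- generate_study(cfg)
  grab <- function(arm) {
    sel <- st$metadata$sample_id[st$metadata$arm == arm &
                                   st$metadata$timepoint == "6h"]
    unlist(lapply(sel, function(sid) {
      ct <- st$samples[[sid]]
      ct$values[ct$population_labels == "CD4Tmem", "pSTAT3"]
    }))
  }
  x1 <- grab("treatment"); x0 <- grab("control")
  expect_gt(min(length(x1), length(x0)), 1e4 / 2)
  se <- sqrt(var(x1) / length(x1) + var(x0) / length(x0))
  expect_lt(abs((mean(x1) - mean(x0)) - 1.0), 3 * se)
})

test_that("baseline generation is arm-neutral even with planted effects", {
  cfg <- study_config(
    n_patients_per_arm = 6, timepoints = c("baseline", "6h"),
    cells_per_sample = 4000, patient_effect_sd = 0,
    effects = list(effect_spec("CD4Tmem", "treatment", "6h",
                               frequency_multiplier = 0.5,
                               signaling_shift = c(pSTAT3 = 1.0))),
    seed = 31)
  st <- generate_study(cfg)
  grab <- function(arm) {
    sel <- st$metadata$sample_id[st$metadata$arm == arm &
                                   st$metadata$timepoint == "baseline"]
    unlist(lapply(sel, function(sid) {
      ct <- st$samples[[sid]]
      ct$values[ct$population_labels == "CD4Tmem", "pSTAT3"]
    }))
  }
  x1 <- grab("treatment"); x0 <- grab("control")
  se <- sqrt(var(x1) / length(x1) + var(x0) / length(x0))
  expect_lt(abs(mean(x1) - mean(x0)), 4 * se)
  ## frequency multiplier must not leak into baseline either
  frac <- function(arm) {
    sel <- st$metadata$sample_id[st$metadata$arm == arm &
                                   st$metadata$timepoint == "baseline"]
    mean(vapply(sel, function(sid)
      mean(st$samples[[sid]]$population_labels == "CD4Tmem"), numeric(1)))
  }
  expect_lt(abs(frac("treatment") - frac("control")), 0.03)
})

test_that("invalid configurations are rejected with configuration errors", {
  expect_error(tiny_config(effects = list(effect_spec("NoSuchPop", "treatment", "6h"))),
               class = "cytoboot_config_error")
  expect_error(tiny_config(effects = list(effect_spec("Tcell", "placebo", "6h"))),
               class = "cytoboot_config_error")
  expect_error(tiny_config(effects = list(effect_spec("Tcell", "treatment", "baseline"))),
               class = "cytoboot_config_error")
  expect_error(tiny_config(cells = -5), class = "cytoboot_config_error")
  expect_error(effect_spec("Tcell", "treatment", "6h", frequency_multiplier = 0),
               class = "cytoboot_config_error")
  bad_pops <- tiny_populations()
  bad_pops[[1]]$base_fraction <- 0.9
  expect_error(
    study_config(n_patients_per_arm = 2, timepoints = c("baseline", "6h"),
                 cells_per_sample = 100, panel = tiny_panel(),
                 populations = bad_pops, surgery_response = list()),
    class = "cytoboot_config_error")
})

test_that("surgery response shifts both arms equally after baseline", {
  resp <- list(Tcell = list(pSTAT3 = c("6h" = 0.7)))
  cfg <- study_config(n_patients_per_arm = 5, timepoints = c("baseline", "6h"),
                      cells_per_sample = 3000, panel = tiny_panel(),
                      populations = tiny_populations(), patient_effect_sd = 0,
                      surgery_response = resp, seed = 13)
  st <- generate_study(cfg)
  mtp <- function(arm, tp) {
    sel <- st$metadata$sample_id[st$metadata$arm == arm & st$metadata$timepoint == tp]
    mean(unlist(lapply(sel, function(sid) {
      ct <- st$samples[[sid]]
      ct$values[ct$population_labels == "Tcell", "pSTAT3"]
    })))
  }
  expect_lt(abs((mtp("control", "6h") - mtp("control", "baseline")) - 0.7), 0.1)
  expect_lt(abs((mtp("treatment", "6h") - mtp("treatment", "baseline")) - 0.7), 0.1)
})
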