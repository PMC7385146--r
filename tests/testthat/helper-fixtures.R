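## Shared fixtures: small panels, studies and cached pipeline runs used
## across test files. All randomness is seeded.

tiny_panel <- function() {
  marker_panel(phenotypic = c("CD45", "CD3", "CD14", "CD19"),
               functional = c("pSTAT3", "pCREB"))
}

## Three well-separated populations on the tiny panel (plus an optional
## neutrophil population for exclusion paths).
tiny_populations <- function(panel = tiny_panel(), with_neutrophils = FALSE) {
  sig <- function(...) {
    ph <- panel$marker[panel$role == "phenotypic"]
    centers <- stats::setNames(rep(0.3, length(ph)), ph)
    high <- c(...)
    centers[names(high)] <- high
    centers
  }
  fb <- stats::setNames(rep(0.8, sum(panel$role == "functional")),
                        panel$marker[panel$role == "functional"])
  pops <- list(
    population_spec("Tcell", "adaptive", sig(CD45 = 4, CD3 = 4),
                    phenotype_spread = 0.3, functional_baseline = fb,
                    base_fraction = if (with_neutrophils) 0.4 else 0.5),
    population_spec("Mono", "innate", sig(CD45 = 4, CD14 = 4),
                    phenotype_spread = 0.3, functional_baseline = fb,
                    base_fraction = 0.3),
    population_spec("Bcell", "adaptive", sig(CD45 = 4, CD19 = 4),
                    phenotype_spread = 0.3, functional_baseline = fb,
                    base_fraction = 0.2)
  )
  if (with_neutrophils) {
    pops <- c(pops, list(
      population_spec("Neutrophil", "neutrophil", sig(CD45 = 2, CD14 = 2),
                      phenotype_spread = 0.3, functional_baseline = fb,
                      base_fraction = 0.1)))
  }
  pops
}

tiny_config <- function(n_per_arm = 3, timepoints = c("baseline", "6h"),
                        cells = 300, seed = 42, effects = list(),
                        with_neutrophils = FALSE, ...) {
  panel <- tiny_panel()
  study_config(n_patients_per_arm = n_per_arm, timepoints = timepoints,
               cells_per_sample = cells, panel = panel,
               populations = tiny_populations(panel, with_neutrophils),
               effects = effects, surgery_response = list(),
               patient_effect_sd = 0, seed = seed, ...)
}

## Hand-built study: one labeled sample with the given per-population cell
## counts; constant marker values per population for exact-arithmetic tests.
manual_study <- function(counts, timepoints = c("baseline", "6h"),
                         populations = NULL, values_by_pop = NULL,
                         sample_meta = NULL) {
  panel <- tiny_panel()
  pops <- names(counts)
  if (is.null(populations)) {
    populations <- data.frame(
      population = pops,
      compartment = ifelse(grepl("Neut", pops), "neutrophil", "adaptive"),
      stringsAsFactors = FALSE)
  }
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = "s1", patient_id = "p1",
                              arm = "control", timepoint = timepoints[1],
                              stringsAsFactors = FALSE)
  }
  samples <- lapply(seq_len(nrow(sample_meta)), function(i) {
    labels <- rep(pops, counts)
    vals <- matrix(0.5, nrow = sum(counts), ncol = nrow(panel),
                   dimnames = list(NULL, panel$marker))
    if (!is.null(values_by_pop)) {
      for (p in pops) {
        vals[labels == p, ] <- matrix(values_by_pop[[p]], sum(labels == p),
                                      nrow(panel), byrow = TRUE)
      }
    }
    cell_table(vals, panel, sample_meta$sample_id[i],
               scale = "arcsinh", population_labels = labels)
  })
  study(samples, sample_meta, timepoints, populations = populations)
}

## Build a minimal cluster_features object directly (bypassing k-means) so
## classifier behavior can be tested on exactly controlled feature values.
manual_features <- function(values, metadata, feature_type = "response",
                            marker = "pSTAT3") {
  columns <- data.frame(column = colnames(values),
                        iteration = 1L, metacluster = seq_len(ncol(values)),
                        feature_type = feature_type, marker = marker,
                        stringsAsFactors = FALSE)
  structure(list(values = values, columns = columns, metadata = metadata,
                 K = ncol(values), B = 1L),
            class = "cluster_features")
}

## Cache heavyweight acceptance simulations so several test blocks can share
## one computation.
.cb_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cb_cache)) assign(key, force(expr), envir = .cb_cache)
  get(key, envir = .cb_cache)
}

## One planted-effect study at the reduced study size used throughout the
## validation suite: 10 vs 10 patients, baseline + 6 h, 2000 cells/sample,
## CD4 memory T cells halved in frequency and shifted +1 arcsinh unit in
## pSTAT3 in the treatment arm after baseline; clustering B = 20, K = 10.
planted_study_run <- function(seed) {
  cfg <- study_config(
    n_patients_per_arm = 10,
    timepoints = c("baseline", "6h"),
    cells_per_sample = 2000,
    effects = list(effect_spec("CD4Tmem", "treatment", "6h",
                               frequency_multiplier = 0.5,
                               signaling_shift = c(pSTAT3 = 1.0))),
    seed = seed)
  st <- generate_study(cfg)
  cl <- cluster_study(st, cluster_config(K = 10, B = 20, seed = seed))
  fe <- build_cluster_features(st, cl)
  r6 <- classify_timepoint(fe, "6h", n_iter = 50, num_trees = 200, seed = seed)
  rb <- classify_timepoint(fe, "baseline", n_iter = 50, num_trees = 200, seed = seed)
  stats6 <- cluster_group_stats(fe, "6h")
  comp <- cluster_composition(st, cl)
  enr <- population_enrichment(comp, stats6, "CD4Tmem")
  top_key <- paste(enr$top_clusters$iteration, enr$top_clusters$metacluster)
  s <- stats6$stats
  s <- s[s$feature_type == "response" & s$marker == "pSTAT3" &
           paste(s$iteration, s$metacluster) %in% top_key & !is.na(s$p), ]
  list(auc_6h = r6$auc, p_6h = r6$p_value, auc_bl = rb$auc, p_bl = rb$p_value,
       enrichment_p = enr$p_value,
       top_signed_logp_positive = mean(s$signed_logp > 0))
}

planted_runs <- function(n_seeds = 20) {
  cached("planted_runs", lapply(seq_len(n_seeds), function(s) {
    suppressWarnings(planted_study_run(1000 + s))
  }))
}

## One no-effect study: 12 vs 12 patients, 1000 cells/sample, B = 20, K = 10.
null_study_run <- function(seed) {
  cfg <- study_config(n_patients_per_arm = 12,
                      timepoints = c("baseline", "6h"),
                      cells_per_sample = 1000, seed = seed)
  st <- generate_study(cfg)
  cl <- cluster_study(st, cluster_config(K = 10, B = 20, seed = seed))
  fe <- build_cluster_features(st, cl)
  r <- classify_timepoint(fe, "6h", n_iter = 50, num_trees = 200, seed = seed)
  list(auc = r$auc, p = r$p_value)
}

null_runs <- function(n_seeds = 50) {
  cached("null_runs", lapply(seq_len(n_seeds), function(s) {
    suppressWarnings(null_study_run(2000 + s))
  }))
}

## Adaptive-compartment-only perturbation: halve naive CD4 T cells and move
## the freed mass into memory CD4 T cells (total adaptive fraction constant,
## so innate frequencies are untouched), plus STAT shifts in both subsets.
adaptive_effect_config <- function(seed, n_per_arm = 8, cells = 800) {
  study_config(
    n_patients_per_arm = n_per_arm,
    timepoints = c("baseline", "6h"),
    cells_per_sample = cells,
    effects = list(
      effect_spec("CD4Tnaive", "treatment", "6h", frequency_multiplier = 0.5,
                  signaling_shift = c(pSTAT5 = 1.5)),
      effect_spec("CD4Tmem", "treatment", "6h",
                  frequency_multiplier = 1 + 0.16 * 0.5 / 0.14,
                  signaling_shift = c(pSTAT3 = 1.5))),
    seed = seed)
}

## Brute-force pairwise AUC oracle.
auc_oracle <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

## Exhaustive rank-assignment oracle for the two-sided rank-sum p-value
## (tie-free inputs): enumerate all C(n, nx) assignments of the pooled ranks.
wilcox_oracle <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  sets <- utils::combn(n, length(x))
  w_all <- colSums(matrix(seq_len(n)[sets], nrow = length(x)))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

## Feature fixture with one separating column plus noise columns,
## used by classifier and atlas tests.
make_logo_fixture <- function(n_per_arm = 10, separation = 3, seed = 1,
                              n_noise = 2) {
  set.seed(seed)
  n <- 2 * n_per_arm
  arm <- rep(c("control", "treatment"), each = n_per_arm)
  X <- cbind(sep = rnorm(n) + separation * (arm == "treatment"),
             matrix(rnorm(n * n_noise), n))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  rownames(X) <- sprintf("%s_%02d_6h", arm, rep(seq_len(n_per_arm), 2))
  meta <- data.frame(sample_id = rownames(X),
                     patient_id = sub("_6h$", "", rownames(X)),
                     arm = arm, timepoint = "6h", stringsAsFactors = FALSE)
  manual_features(X, meta)
}
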