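#' Per-sample cluster count rule, k = sqrt(N/2)
#'
#' The per-sample k-means granularity rule: the number of coarse clusters for
#' a sample of N cells is `sqrt(N/2)`, rounded half away from zero with a
#' floor of 1.
#'
#' @param N number of cells.
#' @return Integer cluster count.
#' @examples
#' kmeans_k_rule(5000)  # 50
#' kmeans_k_rule(2)     # 1
#' @export
kmeans_k_rule <- function(N) {
  pmax(1L, as.integer(round_half_up(sqrt(N / 2))))
}

## k-means++ seeding: successive centers drawn with probability proportional
## to squared distance from the nearest already-chosen center. Returns row
## indices; stops early (length < k) when the distinct points are exhausted.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  ids <- integer(0)
  ids[1L] <- sample.int(n, 1L)
  mind2 <- colSums((t(x) - x[ids[1L], ])^2)
  j <- 1L
  while (j < k) {
    tot <- sum(mind2)
    if (tot <= 0) break  # no distinct points left
    j <- j + 1L
    ids[j] <- sample.int(n, 1L, prob = mind2)
    mind2 <- pmin(mind2, colSums((t(x) - x[ids[j], ])^2))
  }
  ids
}

## k-means with k-means++ seeding and multiple restarts; best fit by total
## within-cluster sum of squares. Not exported; cluster_sample / metacluster
## are the module surface.
kmeanspp <- function(x, k, nstart = 10, iter_max = 100) {
  best <- NULL
  k_eff <- k
  for (s in seq_len(nstart)) {
    ids <- kmeanspp_init(x, k_eff)
    if (length(ids) < k_eff) {
      cb_warn(sprintf("only %d distinct points; k reduced from %d", length(ids), k_eff))
      k_eff <- length(ids)
    }
    if (k_eff == 1L) {
      ctr <- matrix(colMeans(x), 1L, ncol(x), dimnames = list(NULL, colnames(x)))
      return(list(centers = ctr, cluster = rep(1L, nrow(x)), k = 1L,
                  tot.withinss = sum((t(x) - ctr[1L, ])^2)))
    }
    if (k_eff == nrow(x)) {  # one point per cluster; Hartigan-Wong needs k < n
      return(list(centers = x, cluster = seq_len(nrow(x)), k = k_eff,
                  tot.withinss = 0))
    }
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(x, centers = x[ids, , drop = FALSE], iter.max = iter_max)
      ),
      error = function(e) NULL  # e.g. a restart that empties a cluster
    )
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
  }
  if (is.null(best)) cb_stop("k-means failed for every restart", "cytoboot_state_error")
  list(centers = best$centers, cluster = as.integer(best$cluster), k = k_eff,
       tot.withinss = best$tot.withinss)
}

#' Coarse k-means clustering of one sample
#'
#' Clusters one sample's cells in phenotypic-marker space into
#' `k_rule(N)` clusters (k-means++ seeding, Euclidean distance, multiple
#' restarts). Every cell is labeled; nothing is downsampled. When a sample
#' has fewer distinct cells than k, k is reduced with a warning.
#'
#' @param x numeric matrix (cells x phenotypic markers) or a [cell_table()]
#'   (its phenotypic columns are used).
#' @param k_rule function N -> k; default [kmeans_k_rule()].
#' @param seed integer seed; the fit is deterministic given it.
#' @param nstart restarts per fit.
#' @return List with `centers` (k x P), `labels` (per-cell cluster id), `k`.
#' @export
cluster_sample <- function(x, k_rule = kmeans_k_rule, seed = 1L, nstart = 10) {
  if (inherits(x, "cell_table")) {
    x <- x$values[, panel_markers(x$panel, "phenotypic"), drop = FALSE]
  }
  x <- as.matrix(x)
  N <- nrow(x)
  if (N < 1L) cb_stop("no cells to cluster", "cytoboot_state_error")
  k <- min(k_rule(N), N)
  if (k < k_rule(N)) cb_warn(sprintf("k reduced from %d to N = %d", k_rule(N), N))
  fit <- with_seed(seed, kmeanspp(x, k, nstart = nstart))
  list(centers = fit$centers, labels = fit$cluster, k = fit$k)
}

#' Configure bootstrapped metaclustering
#'
#' @param K metacluster count (default 30).
#' @param B metaclustering iterations (default 200).
#' @param k_rule per-sample cluster count rule; default [kmeans_k_rule()].
#' @param exclude_neutrophils drop neutrophil-compartment cells before
#'   clustering (they are analyzed separately); frequencies are still
#'   normalized by the total event count including them.
#' @param nstart k-means restarts per fit.
#' @param seed master seed for the clustering stage.
#' @return A `"cluster_config"` list.
#' @export
cluster_config <- function(K = 30, B = 200, k_rule = kmeans_k_rule,
                           exclude_neutrophils = TRUE, nstart = 10, seed = 1L) {
  if (K < 2) cb_stop("K must be >= 2", "cytoboot_config_error")
  if (B < 1) cb_stop("B must be >= 1", "cytoboot_config_error")
  structure(list(K = as.integer(K), B = as.integer(B), k_rule = k_rule,
                 exclude_neutrophils = isTRUE(exclude_neutrophils),
                 nstart = as.integer(nstart), seed = as.integer(seed)),
            class = "cluster_config")
}

#' Bootstrapped metaclustering of a study
#'
#' Stage 1: each sample is clustered independently with [cluster_sample()]
#' (k = sqrt(N/2)), so every cell of every sample contributes without
#' downsampling. Stage 2: the concatenated sample cluster centers are
#' clustered into `K` metaclusters, repeated `B` times with independent
#' derived seeds to absorb run-to-run k-means variability. Cells inherit a
#' metacluster through their sample cluster's assignment — no cell-level
#' distance computation.
#'
#' @param study a `cytoboot_study` (arcsinh scale).
#' @param config a [cluster_config()].
#' @return A `"cytoboot_clustering"` object: per-sample clusterings
#'   (`sample_clusters`), the stacked center matrix and provenance, and `B`
#'   cluster models each holding `centroids` (K x P) and the center ->
#'   metacluster `assignment`.
#' @export
cluster_study <- function(study, config = cluster_config()) {
  ph <- panel_markers(study$panel, "phenotypic")
  sample_clusters <- list()
  centers_list <- list()
  prov <- list()
  for (sid in study$metadata$sample_id) {
    ct <- study$samples[[sid]]
    keep <- if (config$exclude_neutrophils) !neutrophil_mask(study, ct) else
      rep(TRUE, nrow(ct$values))
    x <- ct$values[keep, ph, drop = FALSE]
    fit <- cluster_sample(x, k_rule = config$k_rule,
                          seed = derive_seed(config$seed, "sample_kmeans", sid),
                          nstart = config$nstart)
    labels <- rep(NA_integer_, nrow(ct$values))
    labels[keep] <- fit$labels
    sample_clusters[[sid]] <- list(centers = fit$centers, labels = labels,
                                   k = fit$k, n_total = nrow(ct$values),
                                   n_clustered = sum(keep))
    centers_list[[sid]] <- fit$centers
    prov[[sid]] <- data.frame(sample_id = sid, cluster = seq_len(fit$k),
                              stringsAsFactors = FALSE)
  }
  all_centers <- do.call(rbind, centers_list)
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  n_distinct <- nrow(unique(all_centers))
  if (n_distinct < config$K) {
    cb_stop(sprintf(
      "only %d distinct sample cluster centers for K = %d metaclusters; choose a smaller K",
      n_distinct, config$K), "cytoboot_config_error")
  }
  models <- lapply(seq_len(config$B), function(b) {
    fit <- with_seed(derive_seed(config$seed, "meta", b),
                     kmeanspp(all_centers, config$K, nstart = config$nstart))
    list(iteration = b, centroids = fit$centers, assignment = fit$cluster)
  })
  structure(list(config = config, sample_clusters = sample_clusters,
                 centers = all_centers, provenance = provenance, models = models),
            class = "cytoboot_clustering")
}

#' @export
print.cytoboot_clustering <- function(x, ...) {
  cat(sprintf(
    "cytoboot_clustering: %d samples, %d pooled sample-cluster centers,\n  %d metaclusters x %d iterations (neutrophils %s)\n",
    length(x$sample_clusters), nrow(x$centers), x$config$K, x$config$B,
    if (x$config$exclude_neutrophils) "excluded" else "included"))
  invisible(x)
}

#' Per-cell metacluster labels for one sample and iteration
#'
#' A cell's metacluster is the metacluster of its sample cluster under the
#' chosen iteration's model; excluded (neutrophil) cells are NA.
#'
#' @param clustering a `"cytoboot_clustering"`.
#' @param sample_id sample to label.
#' @param iteration model iteration in 1..B.
#' @return Integer vector of metacluster ids, one per cell of the sample.
#' @export
assign_cells <- function(clustering, sample_id, iteration = 1L) {
  sc <- clustering$sample_clusters[[sample_id]]
  if (is.null(sc)) cb_stop(paste0("unknown sample '", sample_id, "'"),
                           "cytoboot_consistency_error")
  if (iteration < 1L || iteration > length(clustering$models)) {
    cb_stop("iteration out of range", "cytoboot_consistency_error")
  }
  rows <- which(clustering$provenance$sample_id == sample_id)
  map <- clustering$models[[iteration]]$assignment[rows]
  if (length(map) != sc$k) cb_stop("provenance inconsistent with sample clusters",
                                   "cytoboot_consistency_error")
  map[sc$labels]
}

#' Cluster-level feature matrix across all metaclustering iterations
#'
#' For every sample and every (iteration, metacluster) the matrix holds:
#' \describe{
#'   \item{frequency}{100 x (cells of the sample in the metacluster) /
#'     (total events of the sample, *including* any excluded neutrophils) —
#'     so per sample and iteration the frequency columns sum to
#'     `100 * clustered / total`.}
#'   \item{basal}{median arcsinh intensity of each functional marker over
#'     the sample's cells in the metacluster (missing when empty).}
#'   \item{response}{that median minus the same patient's baseline-sample
#'     median in the same (iteration, metacluster) — iteration-matched
#'     baseline subtraction. Missing when either median is missing or the
#'     patient has no baseline.}
#' }
#'
#' @param study a `cytoboot_study`.
#' @param clustering a `"cytoboot_clustering"` of that study.
#' @return A `"cluster_features"` object: `values` (samples x columns,
#'   with NAs for missing), `columns` metadata (iteration, metacluster,
#'   feature_type, marker), and the sample `metadata`.
#' @export
build_cluster_features <- function(study, clustering) {
  fm <- panel_markers(study$panel, "functional")
  K <- clustering$config$K
  B <- length(clustering$models)
  sids <- study$metadata$sample_id
  nfm <- length(fm)

  freq_names <- as.vector(t(outer(seq_len(B), seq_len(K), function(b, k)
    sprintf("it%03d_mc%02d_freq", b, k))))
  basal_names <- character(B * K * nfm)
  meta_rows <- vector("list", B)
  idx <- 0L
  for (b in seq_len(B)) for (k in seq_len(K)) for (mk in fm) {
    idx <- idx + 1L
    basal_names[idx] <- sprintf("it%03d_mc%02d_basal_%s", b, k, mk)
  }
  FQ <- matrix(NA_real_, length(sids), B * K, dimnames = list(sids, freq_names))
  BS <- matrix(NA_real_, length(sids), B * K * nfm, dimnames = list(sids, basal_names))

  for (si in seq_along(sids)) {
    sid <- sids[si]
    ct <- study$samples[[sid]]
    sc <- clustering$sample_clusters[[sid]]
    n_total <- sc$n_total
    fun_vals <- ct$values[, fm, drop = FALSE]
    rows <- which(clustering$provenance$sample_id == sid)
    for (b in seq_len(B)) {
      map <- clustering$models[[b]]$assignment[rows]
      mc <- map[sc$labels]                      # NA for excluded cells
      counts <- tabulate(mc, nbins = K)
      FQ[si, ((b - 1L) * K + 1L):(b * K)] <- 100 * counts / n_total
      med <- medians_by_group(fun_vals[!is.na(mc), , drop = FALSE],
                              factor(mc[!is.na(mc)], levels = seq_len(K)))
      BS[si, ((b - 1L) * K * nfm + 1L):(b * K * nfm)] <- as.vector(t(med))
    }
  }

  RS <- matrix(NA_real_, length(sids), ncol(BS),
               dimnames = list(sids, sub("_basal_", "_resp_", basal_names)))
  bl <- baseline_timepoint(study)
  m <- study$metadata
  no_baseline <- character(0)
  for (si in seq_along(sids)) {
    if (m$timepoint[si] == bl) next
    bl_sid <- sample_id_for(study, m$patient_id[si], bl)
    if (is.na(bl_sid)) {
      no_baseline <- union(no_baseline, m$patient_id[si])
      next
    }
    RS[si, ] <- BS[si, ] - BS[bl_sid, ]
  }
  if (length(no_baseline) > 0L) {
    cb_warn(paste0("no baseline sample for patient(s): ",
                   paste(no_baseline, collapse = ", "),
                   "; cluster response features are missing for them"))
  }

  columns <- rbind(
    data.frame(column = freq_names,
               iteration = rep(seq_len(B), each = K),
               metacluster = rep(seq_len(K), times = B),
               feature_type = "frequency", marker = "", stringsAsFactors = FALSE),
    data.frame(column = basal_names,
               iteration = rep(seq_len(B), each = K * nfm),
               metacluster = rep(rep(seq_len(K), each = nfm), times = B),
               feature_type = "basal", marker = rep(fm, B * K),
               stringsAsFactors = FALSE),
    data.frame(column = colnames(RS),
               iteration = rep(seq_len(B), each = K * nfm),
               metacluster = rep(rep(seq_len(K), each = nfm), times = B),
               feature_type = "response", marker = rep(fm, B * K),
               stringsAsFactors = FALSE)
  )
  values <- cbind(FQ, BS, RS)
  structure(list(values = values, columns = columns,
                 metadata = study$metadata, K = K, B = B),
            class = "cluster_features")
}

#' @export
print.cluster_features <- function(x, ...) {
  cat(sprintf(
    "cluster_features: %d samples x %d columns (%d iterations x %d metaclusters; frequency + basal + response)\n",
    nrow(x$values), ncol(x$values), x$B, x$K))
  invisible(x)
}

#' Persist a cluster feature matrix (wide CSV + column metadata CSV)
#'
#' @param features a `"cluster_features"`.
#' @param prefix output path prefix; writes `<prefix>_values.csv` and
#'   `<prefix>_columns.csv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_cluster_features <- function(features, prefix) {
  vp <- paste0(prefix, "_values.csv")
  cp <- paste0(prefix, "_columns.csv")
  df <- data.frame(sample_id = rownames(features$values), features$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, vp, row.names = FALSE)
  utils::write.csv(features$columns, cp, row.names = FALSE)
  invisible(c(vp, cp))
}

#' Persist metacluster centroid tables
#'
#' One long CSV: iteration, metacluster, then one column per phenotypic
#' marker.
#'
#' @param clustering a `"cytoboot_clustering"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_models <- function(clustering, path) {
  rows <- lapply(clustering$models, function(mdl) {
    data.frame(iteration = mdl$iteration,
               metacluster = seq_len(nrow(mdl$centroids)),
               mdl$centroids, check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
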