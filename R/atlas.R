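#' Two-dimensional PCA coordinates of the metaclusters
#'
#' Every (iteration, metacluster) is represented by the per-phenotypic-marker
#' median over its pooled cells from all samples, and the clusters x markers
#' median matrix is reduced to two principal components (centered, unscaled —
#' all markers share arcsinh units). These coordinates are the backbone of
#' the immune-cell atlas; statistics are painted on them with
#' [plot_atlas()].
#'
#' @param study a `cytoboot_study`.
#' @param clustering a `"cytoboot_clustering"` of the study.
#' @param mode `"cell_medians"` (median over pooled member cells; default)
#'   or `"centroids"` (median over member sample-cluster centers).
#' @return An `"atlas_coordinates"` object: data.frame `coords` (iteration,
#'   metacluster, PC1, PC2), the `medians` matrix, and the fitted `pca`.
#' @export
atlas_coordinates <- function(study, clustering,
                              mode = c("cell_medians", "centroids")) {
  mode <- match.arg(mode)
  ph <- panel_markers(study$panel, "phenotypic")
  K <- clustering$config$K
  B <- length(clustering$models)
  if (B * K < 3L) cb_stop("PCA needs at least 3 clusters", "cytoboot_state_error")

  med_rows <- vector("list", B)
  for (b in seq_len(B)) {
    if (mode == "cell_medians") {
      pooled <- vector("list", length(study$samples))
      labs <- vector("list", length(study$samples))
      for (si in seq_along(study$metadata$sample_id)) {
        sid <- study$metadata$sample_id[si]
        mc <- assign_cells(clustering, sid, b)
        keep <- !is.na(mc)
        pooled[[si]] <- study$samples[[sid]]$values[keep, ph, drop = FALSE]
        labs[[si]] <- mc[keep]
      }
      med <- medians_by_group(do.call(rbind, pooled),
                              factor(unlist(labs), levels = seq_len(K)))
    } else {
      med <- medians_by_group(clustering$centers[, ph, drop = FALSE],
                              factor(clustering$models[[b]]$assignment,
                                     levels = seq_len(K)))
    }
    med_rows[[b]] <- med
  }
  medians <- do.call(rbind, med_rows)
  rownames(medians) <- as.vector(t(outer(seq_len(B), seq_len(K), function(b, k)
    sprintf("it%03d_mc%02d", b, k))))
  ok <- stats::complete.cases(medians)
  pca <- stats::prcomp(medians[ok, , drop = FALSE], center = TRUE, scale. = FALSE)
  coords <- data.frame(
    iteration = rep(seq_len(B), each = K)[ok],
    metacluster = rep(seq_len(K), times = B)[ok],
    PC1 = pca$x[, 1L], PC2 = pca$x[, 2L],
    stringsAsFactors = FALSE
  )
  rownames(coords) <- rownames(medians)[ok]
  structure(list(coords = coords, medians = medians[ok, , drop = FALSE], pca = pca),
            class = "atlas_coordinates")
}

#' @export
print.atlas_coordinates <- function(x, ...) {
  v <- x$pca$sdev[1:2]^2 / sum(x$pca$sdev^2)
  cat(sprintf("atlas_coordinates: %d clusters; PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
              nrow(x$coords), 100 * v[1], 100 * v[2]))
  invisible(x)
}

#' Per-cluster two-group statistics at one timepoint
#'
#' For every (iteration, metacluster, feature) available at the timepoint, a
#' two-sided Wilcoxon rank-sum test compares the feature between the two
#' arms across samples. `sign_r` is +1 when the treated-arm mean is higher,
#' -1 when lower, 0 on an exact tie, giving the signed map
#' `signed_logp = sign_r * (-log10 p)`; `best_logp` is each cluster's
#' maximum `-log10 p` over its features. Raw p-values are reported (the maps
#' display the best univariate p-value); `adjust = "BH"` optionally applies
#' Benjamini-Hochberg across all tested features.
#'
#' Features missing in more than half of either arm's samples are excluded
#' with a warning.
#'
#' @param features a `"cluster_features"`.
#' @param timepoint timepoint label.
#' @param positive treated-arm label (default lexicographically larger).
#' @param feature_types which feature types to test; default frequency +
#'   response post-baseline, frequency + basal at baseline.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `"group_comparison"` object: data.frame `stats` (iteration,
#'   metacluster, feature_type, marker, p, sign_r, signed_logp) and
#'   data.frame `best` (iteration, metacluster, best_logp).
#' @export
cluster_group_stats <- function(features, timepoint, positive = NULL,
                                feature_types = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- features$metadata
  keep <- m$timepoint == timepoint
  if (!any(keep)) cb_stop(paste0("no samples at timepoint '", timepoint, "'"),
                          "cytoboot_design_error")
  m <- m[keep, , drop = FALSE]
  arms <- sort(unique(m$arm))
  if (length(arms) != 2L) cb_stop("need both arms at the timepoint", "cytoboot_design_error")
  positive <- positive %||% arms[2L]
  resp_cols <- features$columns$column[features$columns$feature_type == "response"]
  is_baseline <- length(resp_cols) == 0L ||
    all(is.na(features$values[m$sample_id, resp_cols]))
  feature_types <- feature_types %||%
    (if (is_baseline) c("frequency", "basal") else c("frequency", "response"))
  cols_meta <- features$columns[features$columns$feature_type %in% feature_types, , drop = FALSE]
  X <- features$values[m$sample_id, cols_meta$column, drop = FALSE]
  pos <- m$arm == positive

  p <- rep(NA_real_, nrow(cols_meta))
  sgn <- rep(NA_real_, nrow(cols_meta))
  excluded <- 0L
  for (j in seq_len(nrow(cols_meta))) {
    x1 <- X[pos, j]; x0 <- X[!pos, j]
    if (mean(is.na(x1)) > 0.5 || mean(is.na(x0)) > 0.5) {
      excluded <- excluded + 1L
      next
    }
    x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
    p[j] <- wilcoxon_rank_sum(x1, x0)
    d <- mean(x1) - mean(x0)
    sgn[j] <- sign(d)
  }
  if (excluded > 0L) {
    cb_warn(sprintf("%d feature(s) missing in > half of an arm at '%s' were excluded",
                    excluded, timepoint))
  }
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  stats_df <- data.frame(cols_meta[, c("iteration", "metacluster", "feature_type", "marker")],
                         p = p, sign_r = sgn,
                         signed_logp = sgn * -log10(p),
                         stringsAsFactors = FALSE)
  ok <- !is.na(stats_df$p)
  best <- stats::aggregate(list(best_logp = -log10(stats_df$p[ok])),
                           by = stats_df[ok, c("iteration", "metacluster")], FUN = max)
  structure(list(stats = stats_df, best = best, timepoint = timepoint,
                 positive = positive),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison @ %s: %d cluster-features tested, max best_logp = %.2f\n",
              x$timepoint, sum(!is.na(x$stats$p)), max(x$best$best_logp)))
  invisible(x)
}

#' Render the immune-cell atlas
#'
#' Scatter of the metaclusters at their PCA coordinates, colored by the
#' chosen statistic: `"best_p"` (best -log10 p per cluster), `"signed"`
#' (sign(r) x -log10 p for one feature type / marker, diverging palette
#' symmetric about zero), or `"phenotype"` (median expression of one
#' phenotypic marker).
#'
#' @param coords an `"atlas_coordinates"`.
#' @param stats a `"group_comparison"` (required for the statistic modes).
#' @param mode one of `"best_p"`, `"signed"`, `"phenotype"`.
#' @param marker functional marker (signed mode, optional: best signed value
#'   across features when omitted) or phenotypic marker (phenotype mode).
#' @param file optional output path (png/svg/pdf by extension).
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_atlas <- function(coords, stats = NULL,
                       mode = c("best_p", "signed", "phenotype"),
                       marker = NULL, file = NULL) {
  if (!inherits(coords, "atlas_coordinates")) {
    cb_stop("`coords` must be atlas_coordinates", "cytoboot_parameter_error")
  }
  mode <- tryCatch(match.arg(mode),
                   error = function(e) cb_stop("unknown atlas mode", "cytoboot_parameter_error"))
  df <- coords$coords
  if (mode == "phenotype") {
    if (is.null(marker) || !marker %in% colnames(coords$medians)) {
      cb_stop("phenotype mode needs a phenotypic `marker`", "cytoboot_parameter_error")
    }
    df$value <- coords$medians[rownames(df), marker]
    gg <- ggplot2::ggplot(df, ggplot2::aes(PC1, PC2, colour = value)) +
      ggplot2::geom_point(size = 1.6) +
      ggplot2::scale_colour_viridis_c(name = marker)
  } else {
    if (is.null(stats)) cb_stop("statistic modes need `stats`", "cytoboot_parameter_error")
    if (mode == "best_p") {
      df <- merge(df, stats$best, by = c("iteration", "metacluster"))
      gg <- ggplot2::ggplot(df, ggplot2::aes(PC1, PC2, colour = best_logp)) +
        ggplot2::geom_point(size = 1.6) +
        ggplot2::scale_colour_viridis_c(name = expression(-log[10] * p))
    } else {
      s <- stats$stats
      if (!is.null(marker)) s <- s[s$marker == marker, , drop = FALSE]
      s <- s[!is.na(s$p), , drop = FALSE]
      agg <- stats::aggregate(list(signed_logp = s$signed_logp),
                              by = s[, c("iteration", "metacluster")],
                              FUN = function(v) v[which.max(abs(v))])
      df <- merge(df, agg, by = c("iteration", "metacluster"))
      lim <- max(abs(df$signed_logp), 1e-12)
      gg <- ggplot2::ggplot(df, ggplot2::aes(PC1, PC2, colour = signed_logp)) +
        ggplot2::geom_point(size = 1.6) +
        ggplot2::scale_colour_gradient2(low = "red", mid = "grey85", high = "blue",
                                        midpoint = 0, limits = c(-lim, lim),
                                        name = expression(sign(r) %*% -log[10] * p))
    }
  }
  gg <- gg + ggplot2::theme_minimal() +
    ggplot2::labs(title = if (is.null(stats)) NULL else
      paste0("Immune cell atlas @ ", stats$timepoint))
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 6, height = 5, dpi = 150)
    return(invisible(gg))
  }
  gg
}

#' True-population composition of each metacluster
#'
#' Counts, per (iteration, metacluster), the ground-truth population of the
#' pooled member cells — the audit table used to check that statistically
#' flagged clusters are made of the population carrying a planted effect.
#'
#' @param study a labeled `cytoboot_study`.
#' @param clustering a `"cytoboot_clustering"`.
#' @return data.frame: iteration, metacluster, population, n_cells.
#' @export
cluster_composition <- function(study, clustering) {
  B <- length(clustering$models)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    labs <- list(); mcs <- list()
    for (sid in study$metadata$sample_id) {
      mc <- assign_cells(clustering, sid, b)
      keep <- !is.na(mc)
      labs[[sid]] <- study$samples[[sid]]$population_labels[keep]
      mcs[[sid]] <- mc[keep]
    }
    tab <- table(metacluster = unlist(mcs), population = unlist(labs))
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0L, , drop = FALSE]
    out[[b]] <- data.frame(iteration = b,
                           metacluster = as.integer(df$metacluster),
                           population = df$population, n_cells = df$Freq,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Enrichment of a population among the most significant clusters
#'
#' Takes the top `top_fraction` of clusters by `best_logp` and tests, with a
#' one-sided Fisher exact test on cell counts, whether cells of
#' `population` are over-represented in those clusters relative to the rest.
#'
#' @param composition output of [cluster_composition()].
#' @param stats a `"group_comparison"`.
#' @param population population of interest.
#' @param top_fraction fraction of clusters taken as "top" (default 0.1).
#' @return List: `p_value` (Fisher), `odds_ratio`, `top_clusters`
#'   (data.frame of the selected clusters).
#' @export
population_enrichment <- function(composition, stats, population,
                                  top_fraction = 0.1) {
  best <- stats$best
  n_top <- max(1L, ceiling(nrow(best) * top_fraction))
  ord <- order(best$best_logp, decreasing = TRUE)
  top <- best[ord[seq_len(n_top)], c("iteration", "metacluster")]
  key <- function(df) paste(df$iteration, df$metacluster)
  in_top <- key(composition) %in% key(top)
  is_pop <- composition$population == population
  tab <- matrix(c(sum(composition$n_cells[in_top & is_pop]),
                  sum(composition$n_cells[in_top & !is_pop]),
                  sum(composition$n_cells[!in_top & is_pop]),
                  sum(composition$n_cells[!in_top & !is_pop])),
                nrow = 2L, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       top_clusters = best[ord[seq_len(n_top)], , drop = FALSE])
}
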