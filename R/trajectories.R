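#' Per-sample gated-feature vectors
#'
#' Wide matrix of the gated-population features used for trajectory
#' embedding: population frequencies plus per-(population, functional
#' marker) basal median intensities, one row per sample. Column names are
#' `freq_<population>` and `sig_<population>_<marker>`.
#'
#' @param study a labeled `cytoboot_study`.
#' @return Numeric matrix, rownames = sample ids, with attribute
#'   `"compartment"`: the compartment of each column's population.
#' @export
sample_feature_vectors <- function(study) {
  fr <- population_frequencies(study)
  sg <- population_signaling(study)
  sg <- sg[sg$feature_type == "basal", , drop = FALSE]
  sids <- study$metadata$sample_id
  fr_wide <- stats::reshape(
    transform(fr[, c("sample_id", "population", "value")],
              col = paste0("freq_", population))[, c("sample_id", "col", "value")],
    idvar = "sample_id", timevar = "col", direction = "wide")
  sg_wide <- stats::reshape(
    transform(sg[, c("sample_id", "population", "marker", "value")],
              col = paste0("sig_", population, "_", marker))[, c("sample_id", "col", "value")],
    idvar = "sample_id", timevar = "col", direction = "wide")
  to_mat <- function(w) {
    mat <- as.matrix(w[, -1L, drop = FALSE])
    colnames(mat) <- sub("^value\\.", "", colnames(mat))
    rownames(mat) <- w$sample_id
    mat[sids, , drop = FALSE]
  }
  out <- cbind(to_mat(fr_wide), to_mat(sg_wide))
  comp <- compartment_of(study)
  pop_of_col <- sub("^(freq|sig)_", "", colnames(out))
  pop_of_col <- vapply(strsplit(pop_of_col, "_"), `[[`, character(1), 1L)
  attr(out, "compartment") <- unname(comp[pop_of_col])
  out
}

#' Baseline-subtract per-patient feature vectors
#'
#' Subtracts each patient's baseline row from all of that patient's rows, so
#' baseline samples map exactly to the zero vector and post-baseline rows
#' become within-patient changes. Patients without a baseline sample are
#' dropped with a warning. Idempotent on already-normalized data.
#'
#' @param x samples x features matrix (rownames = sample ids).
#' @param study the `cytoboot_study` giving patient / timepoint structure.
#' @return Matrix of the same shape (minus dropped patients), same attribute
#'   `"compartment"` as `x` if present.
#' @export
baseline_normalize <- function(x, study) {
  bl <- baseline_timepoint(study)
  m <- study$metadata[match(rownames(x), study$metadata$sample_id), , drop = FALSE]
  out <- x
  keep <- rep(TRUE, nrow(x))
  dropped <- character(0)
  for (i in seq_len(nrow(x))) {
    bl_sid <- sample_id_for(study, m$patient_id[i], bl)
    if (is.na(bl_sid) || !bl_sid %in% rownames(x)) {
      keep[i] <- FALSE
      dropped <- union(dropped, m$patient_id[i])
      next
    }
    out[i, ] <- x[i, ] - x[bl_sid, ]
  }
  if (length(dropped) > 0L) {
    cb_warn(paste0("no baseline for patient(s): ", paste(dropped, collapse = ", "),
                   "; excluded from trajectories"))
  }
  res <- out[keep, , drop = FALSE]
  attr(res, "compartment") <- attr(x, "compartment")
  res
}

#' One-dimensional Isomap embedding
#'
#' Classical Isomap: symmetrized k-nearest-neighbor graph on Euclidean
#' distances, shortest-path geodesic distances, and an MDS eigen-embedding.
#' Errors when the neighborhood graph is disconnected, naming the component
#' sizes. Eigen-embeddings are sign-ambiguous; orientation conventions are
#' applied by the caller (see [trajectory_embedding()]).
#'
#' @param x observations x features matrix.
#' @param n_neighbors neighborhood size k (default 10).
#' @param n_components embedding dimension (default 1).
#' @return Matrix of embedding coordinates (observations x components),
#'   rownames preserved.
#' @export
isomap_embed <- function(x, n_neighbors = 10, n_components = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < n_neighbors + 2L) {
    cb_stop(sprintf("need >= n_neighbors + 2 = %d points, got %d", n_neighbors + 2L, n),
            "cytoboot_parameter_error")
  }
  d <- stats::dist(x)
  dm <- as.matrix(d)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(dm[i, ])[2:(n_neighbors + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    cb_stop(paste0("neighborhood graph is disconnected (component sizes: ",
                   paste(sort(comp$csize, decreasing = TRUE), collapse = ", "),
                   "); increase n_neighbors"),
            "cytoboot_state_error")
  }
  fit <- vegan::isomap(d, ndim = n_components, k = n_neighbors)
  pts <- fit$points[, seq_len(n_components), drop = FALSE]
  rownames(pts) <- rownames(x)
  colnames(pts) <- paste0("dim", seq_len(n_components))
  pts
}

#' Least-squares linear extension of an embedding
#'
#' Fits the linear map feature-space -> embedding coordinate by least
#' squares on the training points, falling back to a lightly
#' ridge-regularized solve (with a warning) when the feature matrix is rank
#' deficient. The returned map is affine-consistent, so applying it to
#' convex combinations of consecutive timepoints yields continuous
#' interpolated trajectories between observed snapshots.
#'
#' @param x training feature matrix.
#' @param coords embedding coordinates of the same rows (vector or 1-column
#'   matrix).
#' @return A `"linear_extension"` object; use [predict()] on new feature
#'   vectors.
#' @export
linear_extension <- function(x, coords) {
  x <- as.matrix(x)
  y <- as.numeric(as.matrix(coords)[, 1L])
  if (nrow(x) != length(y)) cb_stop("x and coords must have matching rows",
                                    "cytoboot_parameter_error")
  A <- cbind(`(Intercept)` = 1, x)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    cb_warn("feature matrix is rank deficient; using ridge-regularized fit")
    lambda <- 1e-8 * sum(diag(crossprod(A))) / ncol(A)
    beta <- solve(crossprod(A) + diag(lambda, ncol(A)), crossprod(A, y))
  } else {
    beta <- qr.coef(qrA, y)
  }
  structure(list(coef = as.numeric(beta), features = colnames(x)),
            class = "linear_extension")
}

#' @param object a `"linear_extension"`.
#' @param newdata feature matrix (or vector) to map.
#' @param ... unused.
#' @rdname linear_extension
#' @export
predict.linear_extension <- function(object, newdata, ...) {
  nd <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  as.numeric(cbind(1, nd) %*% object$coef)
}

#' Innate / adaptive trajectory embedding of a study
#'
#' The per-sample gated feature vectors are baseline-normalized (each
#' patient's baseline maps to the zero vector), split into innate and
#' adaptive feature groups by population compartment (neutrophils count as
#' innate), and each group is embedded to one Isomap dimension: the innate X
#' axis and the adaptive Y axis of the trajectory plots. Each axis's sign is
#' fixed so the group-median coordinate at the first post-baseline timepoint
#' is at least the baseline median.
#'
#' @param study a labeled `cytoboot_study`.
#' @param n_neighbors Isomap neighborhood size.
#' @param compartment_map optional named vector feature-column ->
#'   `"innate"`/`"adaptive"` overriding the default population-compartment
#'   split.
#' @return A `"trajectory_embedding"`: data.frame `coords` (sample_id,
#'   patient_id, arm, timepoint, x_innate, y_adaptive), plus the fitted
#'   [linear_extension()] per axis for interpolation.
#' @export
trajectory_embedding <- function(study, n_neighbors = 10, compartment_map = NULL) {
  x <- sample_feature_vectors(study)
  xn <- baseline_normalize(x, study)
  comp <- attr(xn, "compartment")
  comp[comp == "neutrophil"] <- "innate"
  if (!is.null(compartment_map)) {
    hit <- intersect(names(compartment_map), colnames(xn))
    comp[match(hit, colnames(xn))] <- compartment_map[hit]
  }
  if (!all(comp %in% c("innate", "adaptive"))) {
    cb_stop("every feature needs an 'innate' or 'adaptive' compartment",
            "cytoboot_config_error")
  }
  m <- study$metadata[match(rownames(xn), study$metadata$sample_id), , drop = FALSE]
  bl <- baseline_timepoint(study)
  first_post <- study$timepoints[2L]
  embed_axis <- function(cols) {
    pts <- isomap_embed(xn[, cols, drop = FALSE], n_neighbors = n_neighbors,
                        n_components = 1)[, 1L]
    med_post <- stats::median(pts[m$timepoint == first_post])
    med_bl <- stats::median(pts[m$timepoint == bl])
    if (med_post < med_bl) pts <- -pts
    pts
  }
  xi <- embed_axis(comp == "innate")
  ya <- embed_axis(comp == "adaptive")
  coords <- data.frame(sample_id = rownames(xn), patient_id = m$patient_id,
                       arm = m$arm, timepoint = m$timepoint,
                       x_innate = xi, y_adaptive = ya,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coords = coords,
                 map_innate = linear_extension(xn[, comp == "innate", drop = FALSE], xi),
                 map_adaptive = linear_extension(xn[, comp == "adaptive", drop = FALSE], ya),
                 n_neighbors = n_neighbors),
            class = "trajectory_embedding")
}

#' @export
print.trajectory_embedding <- function(x, ...) {
  cat(sprintf("trajectory_embedding: %d samples, %d patients (k = %d neighbors)\n",
              nrow(x$coords), length(unique(x$coords$patient_id)), x$n_neighbors))
  invisible(x)
}

#' Plot group-median immune trajectories
#'
#' Median innate (X) and adaptive (Y) coordinates per arm and timepoint,
#' connected in timepoint order; individual samples as faint points.
#'
#' @param embedding a `"trajectory_embedding"`.
#' @param study the `cytoboot_study` (for timepoint order).
#' @param file optional output image path.
#' @return The ggplot object.
#' @export
plot_trajectories <- function(embedding, study, file = NULL) {
  df <- embedding$coords
  df$timepoint <- factor(df$timepoint, levels = study$timepoints)
  med <- stats::aggregate(df[, c("x_innate", "y_adaptive")],
                          by = df[, c("arm", "timepoint")], FUN = stats::median)
  med <- med[order(med$arm, med$timepoint), ]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x_innate, y_adaptive, colour = arm)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_path(data = med, linewidth = 1) +
    ggplot2::geom_point(data = med, size = 2) +
    ggplot2::labs(x = "innate axis (X)", y = "adaptive axis (Y)") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 6, height = 5, dpi = 150)
    return(invisible(gg))
  }
  gg
}
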