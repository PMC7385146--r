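#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' AUC is computed as the probability that a random treated sample scores
#' above a random control sample, with ties counting one half:
#' `(#{score_t > score_c} + 0.5 * #ties) / (n_t * n_c)`.
#'
#' @param scores numeric scores (e.g. predicted treatment probabilities).
#' @param labels arm label per score.
#' @param positive label of the treated arm; defaults to the
#'   lexicographically larger of the two labels.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c("c", "c", "t", "t"), positive = "t")  # 0.75
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) cb_stop("roc_auc needs exactly two groups", "cytoboot_parameter_error")
  positive <- positive %||% lev[2L]
  if (!positive %in% lev) cb_stop("`positive` is not a label level", "cytoboot_parameter_error")
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # midranks handle ties as 0.5
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution (all rank assignments) when the pooled size is at
#' most 20 and there are no ties; otherwise the normal approximation with
#' tie and continuity correction. Symmetric in its arguments.
#'
#' @param x,y numeric samples.
#' @return Two-sided p-value in (0, 1\].
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    cb_stop("both samples must be nonempty", "cytoboot_parameter_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 20L
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
  if (!is.finite(p)) p <- 1  # fully tied data: zero-variance normal approximation
  min(p, 1)
}

#' Repeated leave-group-out random-forest classification at one timepoint
#'
#' Restricts a [build_cluster_features()] matrix to one timepoint (one row
#' per patient) and repeatedly (1) splits the patients into stratified
#' halves, (2) trains a random forest on one half, (3) scores the held-out
#' half with the predicted probability of the treated arm. Each sample's
#' final score is the median of its held-out predictions; iterations are
#' topped up (with derived seeds) until every sample has been held out at
#' least once. The per-sample scores give the ROC/AUC (Mann-Whitney) and a
#' two-sided rank-sum p-value for arm separation.
#'
#' Feature handling: post-baseline timepoints use frequency + response
#' columns; the baseline timepoint (which has no baseline-subtracted
#' responses) uses frequency + basal columns, keeping the machinery
#' otherwise identical. All-missing columns are dropped with a warning;
#' remaining missing values are imputed with the training-half median per
#' feature inside each iteration, so no test information leaks into
#' training.
#'
#' @param features a `"cluster_features"` object.
#' @param timepoint timepoint label to classify.
#' @param n_iter cross-validation iterations (default 200).
#' @param seed integer seed for split and forest randomness.
#' @param num_trees trees per forest.
#' @param positive treated-arm label; default the lexicographically larger.
#' @param feature_types override of the feature-type selection.
#' @param coverage when `TRUE` (default) iterations are topped up until every
#'   sample has at least one held-out prediction; when `FALSE` samples never
#'   held out are dropped from the result with a warning.
#' @return A `"classifier_result"`: `timepoint`, `probabilities` (data.frame
#'   sample_id, patient_id, arm, probability), `auc`, `p_value`,
#'   `n_iterations`.
#' @export
classify_timepoint <- function(features, timepoint, n_iter = 200, seed = 1L,
                               num_trees = 500, positive = NULL,
                               feature_types = NULL, coverage = TRUE) {
  m <- features$metadata
  keep <- m$timepoint == timepoint
  if (!any(keep)) cb_stop(paste0("no samples at timepoint '", timepoint, "'"),
                          "cytoboot_design_error")
  m <- m[keep, , drop = FALSE]
  arms <- sort(unique(m$arm))
  if (length(arms) != 2L) cb_stop("need exactly two arms at the timepoint",
                                  "cytoboot_design_error")
  if (any(table(m$arm) < 2L)) cb_stop("each arm needs >= 2 patients at the timepoint",
                                      "cytoboot_design_error")
  positive <- positive %||% arms[2L]

  is_baseline <- !any(features$columns$feature_type == "response") ||
    all(is.na(features$values[keep,
      features$columns$column[features$columns$feature_type == "response"]]))
  feature_types <- feature_types %||%
    (if (is_baseline) c("frequency", "basal") else c("frequency", "response"))
  cols <- features$columns$column[features$columns$feature_type %in% feature_types]
  X <- features$values[m$sample_id, cols, drop = FALSE]

  all_na <- apply(X, 2L, function(v) all(is.na(v)))
  if (any(all_na)) {
    cb_warn(sprintf("dropping %d all-missing feature column(s) at '%s'",
                    sum(all_na), timepoint))
    X <- X[, !all_na, drop = FALSE]
  }
  if (ncol(X) == 0L) cb_stop("no usable feature columns", "cytoboot_state_error")

  n <- nrow(X)
  y <- factor(m$arm, levels = arms)
  preds <- vector("list", n)
  half_split <- function(it_seed) {
    with_seed(it_seed, {
      train <- logical(n)
      for (a in arms) {
        ia <- which(m$arm == a)
        train[sample(ia, ceiling(length(ia) / 2))] <- TRUE
      }
      train
    })
  }
  run_iteration <- function(b) {
    it_seed <- derive_seed(seed, "logo", b)
    train <- half_split(it_seed)
    if (length(unique(y[train])) < 2L || !any(!train)) return(invisible(NULL))
    Xtr <- X[train, , drop = FALSE]
    med <- apply(Xtr, 2L, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    impute <- function(A) {
      nas <- which(is.na(A), arr.ind = TRUE)
      if (nrow(nas)) A[nas] <- med[nas[, 2L]]
      A
    }
    fit <- ranger::ranger(x = impute(Xtr), y = y[train], probability = TRUE,
                          num.trees = num_trees, min.node.size = 1L,
                          seed = it_seed, num.threads = 1L, verbose = FALSE)
    test <- which(!train)
    pr <- stats::predict(fit, data = impute(X[test, , drop = FALSE]),
                         num.threads = 1L)$predictions[, positive]
    for (j in seq_along(test)) {
      preds[[test[j]]] <<- c(preds[[test[j]]], pr[j])
    }
    invisible(NULL)
  }
  for (b in seq_len(n_iter)) run_iteration(b)
  extra <- 0L
  if (coverage) {
    while (any(vapply(preds, length, integer(1)) == 0L) && extra < 200L) {
      extra <- extra + 1L
      run_iteration(n_iter + extra)
    }
    if (any(vapply(preds, length, integer(1)) == 0L)) {
      cb_stop("some samples never entered a test half", "cytoboot_state_error")
    }
  }
  tested <- vapply(preds, length, integer(1)) > 0L
  if (!all(tested)) {
    cb_warn(sprintf("%d sample(s) never held out were dropped", sum(!tested)))
    m <- m[tested, , drop = FALSE]
    preds <- preds[tested]
  }
  prob <- vapply(preds, stats::median, numeric(1))
  auc <- roc_auc(prob, m$arm, positive = positive)
  p <- wilcoxon_rank_sum(prob[m$arm == positive], prob[m$arm != positive])
  structure(list(timepoint = timepoint,
                 probabilities = data.frame(sample_id = m$sample_id,
                                            patient_id = m$patient_id,
                                            arm = m$arm, probability = prob,
                                            n_predictions = vapply(preds, length, integer(1)),
                                            stringsAsFactors = FALSE),
                 auc = auc, p_value = p, n_iterations = n_iter + extra,
                 positive = positive),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("classifier_result @ %s: AUC = %.3f, p = %.3g (%d LOGO iterations, treated arm '%s')\n",
              x$timepoint, x$auc, x$p_value, x$n_iterations, x$positive))
  invisible(x)
}

#' Write a classifier result as JSON
#'
#' @param result a `"classifier_result"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_classifier_result <- function(result, path) {
  jsonlite::write_json(
    list(timepoint = result$timepoint, auc = result$auc,
         p_value = result$p_value, n_iterations = result$n_iterations,
         probabilities = result$probabilities),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
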