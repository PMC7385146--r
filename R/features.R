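#' Arcsinh transform of raw cytometry intensities
#'
#' The standard variance-stabilizing transform for cytometry,
#' `asinh(x / cofactor)`. The mass-cytometry convention of cofactor 5 is the
#' default. `cell_table`s carry a scale flag and refuse a second transform —
#' silently double-transforming is a classic cytometry bug.
#'
#' @param x numeric vector/matrix of raw intensities, or a [cell_table()]
#'   with `scale = "raw"`.
#' @param cofactor positive scalar divisor.
#' @return Same shape as `x`, on the arcsinh scale; for a `cell_table` the
#'   scale flag flips to `"arcsinh"`.
#' @examples
#' arcsinh_transform(5, cofactor = 5)  # log(1 + sqrt(2)) = 0.8813736
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    cb_stop("cofactor must be a positive scalar", "cytoboot_parameter_error")
  }
  if (inherits(x, "cell_table")) {
    if (x$scale == "arcsinh") {
      cb_stop(paste0("sample '", x$sample_id, "' is already on the arcsinh scale"),
              "cytoboot_state_error")
    }
    x$values <- asinh(x$values / cofactor)
    x$scale <- "arcsinh"
    return(x)
  }
  asinh(x / cofactor)
}

#' @rdname arcsinh_transform
#' @description `arcsinh_inverse` maps back to the raw scale,
#'   `cofactor * sinh(x)`.
#' @export
arcsinh_inverse <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    cb_stop("cofactor must be a positive scalar", "cytoboot_parameter_error")
  }
  if (inherits(x, "cell_table")) {
    if (x$scale == "raw") cb_stop("sample is already on the raw scale", "cytoboot_state_error")
    x$values <- cofactor * sinh(x$values)
    x$scale <- "raw"
    return(x)
  }
  cofactor * sinh(x)
}

#' Per-sample population frequencies
#'
#' Mononuclear (non-neutrophil) populations are expressed as a percentage of
#' the sample's non-neutrophil cells and sum to 100 per sample; the
#' neutrophil compartment is expressed as a percentage of all cells. Uses the
#' per-cell ground-truth labels (the stand-in for manual gating).
#'
#' @param study a `cytoboot_study` with population labels.
#' @return A data.frame: `sample_id`, `population`, `feature_type`
#'   (`"frequency"`), `value` (percent).
#' @export
population_frequencies <- function(study) {
  pops <- study$populations
  if (is.null(pops)) cb_stop("study carries no population dictionary", "cytoboot_state_error")
  pop_names <- pops$population
  neut <- pop_names[pops$compartment == "neutrophil"]
  mono <- setdiff(pop_names, neut)
  rows <- lapply(study$metadata$sample_id, function(sid) {
    ct <- study$samples[[sid]]
    if (is.null(ct$population_labels)) {
      cb_stop(paste0("sample '", sid, "' has no population labels"), "cytoboot_state_error")
    }
    lab <- factor(ct$population_labels, levels = pop_names)
    counts <- table(lab)
    n_all <- length(lab)
    n_mono <- sum(counts[mono])
    value <- c(if (n_mono > 0) 100 * counts[mono] / n_mono else rep(NA_real_, length(mono)),
               100 * counts[neut] / n_all)
    data.frame(sample_id = sid, population = c(mono, neut),
               feature_type = "frequency", value = as.numeric(value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-population signaling features
#'
#' For every (sample, population, functional marker) the basal activity is
#' the median arcsinh intensity over that population's cells. For
#' post-baseline samples the signaling response is the difference of that
#' median from the same patient's baseline median within the same population
#' — the "arcsinh ratio" convention: a difference of arcsinh-scale medians,
#' never a quotient. Populations empty in a sample yield missing values
#' (never zero); patients without a baseline sample get no responses and a
#' warning.
#'
#' @param study a `cytoboot_study` on the arcsinh scale, with labels.
#' @return A data.frame: `sample_id`, `population`, `marker`, `feature_type`
#'   (`"basal"` or `"response"`), `value`. Responses exist only for
#'   post-baseline samples of patients with a baseline sample.
#' @export
population_signaling <- function(study) {
  pops <- study$populations
  if (is.null(pops)) cb_stop("study carries no population dictionary", "cytoboot_state_error")
  pop_names <- pops$population
  fm <- panel_markers(study$panel, "functional")
  bl <- baseline_timepoint(study)

  basal <- lapply(study$metadata$sample_id, function(sid) {
    ct <- study$samples[[sid]]
    if (ct$scale != "arcsinh") {
      cb_stop("signaling features require arcsinh-scale data", "cytoboot_state_error")
    }
    if (is.null(ct$population_labels)) {
      cb_stop(paste0("sample '", sid, "' has no population labels"), "cytoboot_state_error")
    }
    med <- medians_by_group(ct$values[, fm, drop = FALSE],
                            factor(ct$population_labels, levels = pop_names))
    data.frame(sample_id = sid,
               population = rep(pop_names, times = length(fm)),
               marker = rep(fm, each = length(pop_names)),
               feature_type = "basal", value = as.vector(med),
               stringsAsFactors = FALSE)
  })
  basal <- do.call(rbind, basal)

  m <- study$metadata
  resp <- list()
  no_baseline <- character(0)
  for (i in seq_len(nrow(m))) {
    if (m$timepoint[i] == bl) next
    bl_sid <- sample_id_for(study, m$patient_id[i], bl)
    if (is.na(bl_sid)) {
      no_baseline <- union(no_baseline, m$patient_id[i])
      next
    }
    post <- basal[basal$sample_id == m$sample_id[i], ]
    base <- basal[basal$sample_id == bl_sid, ]
    stopifnot(identical(post$population, base$population),
              identical(post$marker, base$marker))
    post$feature_type <- "response"
    post$value <- post$value - base$value
    resp[[m$sample_id[i]]] <- post
  }
  if (length(no_baseline) > 0L) {
    cb_warn(paste0("no baseline sample for patient(s): ",
                   paste(no_baseline, collapse = ", "),
                   "; their signaling responses are omitted"))
  }
  out <- rbind(basal, do.call(rbind, resp))
  rownames(out) <- NULL
  out
}

#' Export gated-population features as long-format CSV
#'
#' One row per (sample, unit, feature type, marker) with columns
#' `sample_id`, `unit_id`, `feature_type`, `marker`, `value`.
#'
#' @param study a `cytoboot_study`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_features <- function(study, path) {
  fr <- population_frequencies(study)
  fr <- data.frame(sample_id = fr$sample_id, unit_id = fr$population,
                   feature_type = fr$feature_type, marker = "", value = fr$value,
                   stringsAsFactors = FALSE)
  sg <- population_signaling(study)
  sg <- data.frame(sample_id = sg$sample_id, unit_id = sg$population,
                   feature_type = sg$feature_type, marker = sg$marker,
                   value = sg$value, stringsAsFactors = FALSE)
  utils::write.csv(rbind(fr, sg), path, row.names = FALSE)
  invisible(path)
}
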