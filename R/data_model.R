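#' One sample's single-cell event table
#'
#' A `cell_table` holds one sample's cells x markers matrix together with the
#' marker panel (roles), an explicit intensity-scale flag, and optional
#' per-cell population labels (the synthetic ground truth that stands in for
#' manual gating). Cells containing any non-finite value are dropped with a
#' message — downstream statistics assume complete rows.
#'
#' @param values numeric matrix, cells x markers; column names must cover the
#'   panel markers. Columns are reordered to the canonical panel order so
#'   downstream results never depend on on-disk column order.
#' @param panel a [marker_panel()].
#' @param sample_id sample identifier.
#' @param scale `"arcsinh"` or `"raw"`; which scale `values` are on.
#' @param population_labels optional character vector, one label per cell.
#' @return An object of class `"cell_table"` with elements `sample_id`,
#'   `values`, `panel`, `scale`, `population_labels`.
#' @export
cell_table <- function(values, panel, sample_id, scale = c("arcsinh", "raw"),
                       population_labels = NULL) {
  panel <- check_panel(panel)
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) cb_stop("cell values must be numeric", "cytoboot_format_error")
  missing <- setdiff(panel$marker, colnames(values))
  if (length(missing) > 0L) {
    cb_stop(paste0("sample '", sample_id, "' is missing panel marker(s): ",
                   paste(missing, collapse = ", ")),
            "cytoboot_format_error")
  }
  values <- values[, panel$marker, drop = FALSE]
  if (nrow(values) < 1L) cb_stop("cell table has no cells", "cytoboot_format_error")
  if (!is.null(population_labels)) {
    population_labels <- as.character(population_labels)
    if (length(population_labels) != nrow(values)) {
      cb_stop("population_labels length must equal the number of cells",
              "cytoboot_format_error")
    }
  }
  bad <- !apply(is.finite(values), 1L, all)
  if (any(bad)) {
    message(sprintf("cell_table '%s': dropped %d cell(s) with non-finite values",
                    sample_id, sum(bad)))
    values <- values[!bad, , drop = FALSE]
    if (!is.null(population_labels)) population_labels <- population_labels[!bad]
    if (nrow(values) < 1L) cb_stop("all cells dropped as non-finite", "cytoboot_format_error")
  }
  structure(
    list(sample_id = as.character(sample_id), values = values, panel = panel,
         scale = scale, population_labels = population_labels),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table '%s': %d cells x %d markers (%s scale)%s\n",
              x$sample_id, nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$population_labels)) "" else ", labeled"))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$values)

#' A two-arm longitudinal mass-cytometry study
#'
#' Binds per-sample [cell_table()]s to their sample metadata (patient, arm,
#' timepoint), the shared marker panel, the timepoint ordering (baseline
#' first), and the population/compartment dictionary used for neutrophil
#' exclusion and the innate/adaptive trajectory split.
#'
#' @param samples list of `cell_table`s.
#' @param metadata data.frame with columns `sample_id`, `patient_id`, `arm`,
#'   `timepoint`; one row per sample.
#' @param timepoints ordered character vector of timepoint labels, first
#'   entry is the baseline.
#' @param populations optional data.frame with columns `population` and
#'   `compartment` (one of `"innate"`, `"adaptive"`, `"neutrophil"`).
#' @return An object of class `"cytoboot_study"`.
#' @export
study <- function(samples, metadata, timepoints, populations = NULL) {
  req <- c("sample_id", "patient_id", "arm", "timepoint")
  if (!all(req %in% names(metadata))) {
    cb_stop(paste0("metadata must have columns: ", paste(req, collapse = ", ")),
            "cytoboot_consistency_error")
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  for (cc in req) metadata[[cc]] <- as.character(metadata[[cc]])
  if (length(samples) == 0L) cb_stop("study has no samples", "cytoboot_consistency_error")
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  names(samples) <- ids
  if (anyDuplicated(ids)) cb_stop("duplicate sample_id among cell tables",
                                  "cytoboot_consistency_error")
  if (!setequal(ids, metadata$sample_id) || nrow(metadata) != length(ids)) {
    cb_stop("metadata sample_ids must match the cell tables one-to-one",
            "cytoboot_consistency_error")
  }
  dup <- duplicated(metadata[, c("patient_id", "timepoint")])
  if (any(dup)) {
    cb_stop(paste0("duplicate (patient, timepoint) pair(s): ",
                   paste(unique(paste(metadata$patient_id[dup],
                                      metadata$timepoint[dup])), collapse = "; ")),
            "cytoboot_consistency_error")
  }
  timepoints <- as.character(timepoints)
  if (length(timepoints) < 2L) cb_stop("need at least 2 timepoints", "cytoboot_consistency_error")
  if (!all(metadata$timepoint %in% timepoints)) {
    cb_stop("metadata contains timepoints not in `timepoints`", "cytoboot_consistency_error")
  }
  panel0 <- samples[[1L]]$panel
  same <- vapply(samples, function(s) identical(s$panel$marker, panel0$marker) &&
                   identical(s$panel$role, panel0$role), logical(1))
  if (!all(same)) cb_stop("all samples must share an identical marker panel",
                          "cytoboot_consistency_error")
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(
    list(samples = samples, metadata = metadata, panel = panel0,
         timepoints = timepoints, populations = populations),
    class = "cytoboot_study"
  )
}

#' @export
print.cytoboot_study <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("cytoboot_study: %d samples, %d patients, arms {%s}, %d timepoints (%s)\n",
              nrow(m), length(unique(m$patient_id)),
              paste(sort(unique(m$arm)), collapse = ", "),
              length(x$timepoints), paste(x$timepoints, collapse = " < ")))
  cells <- vapply(x$samples, function(s) nrow(s$values), numeric(1))
  cat(sprintf("  cells per sample: %d-%d; panel: %d phenotypic + %d functional markers\n",
              min(cells), max(cells),
              sum(x$panel$role == "phenotypic"), sum(x$panel$role == "functional")))
  invisible(x)
}

#' Baseline timepoint label of a study
#' @param study a `cytoboot_study`.
#' @return The first (baseline) timepoint label.
#' @export
baseline_timepoint <- function(study) study$timepoints[1L]

#' Sample id of a patient's sample at a timepoint (NA when absent)
#' @noRd
sample_id_for <- function(study, patient_id, timepoint) {
  m <- study$metadata
  hit <- m$sample_id[m$patient_id == patient_id & m$timepoint == timepoint]
  if (length(hit) == 1L) hit else NA_character_
}

#' Map population label -> compartment, defaulting to the study dictionary
#' @noRd
compartment_of <- function(study, populations = study$populations) {
  if (is.null(populations)) return(NULL)
  stats::setNames(as.character(populations$compartment),
                  as.character(populations$population))
}

#' Per-cell logical mask of neutrophil-compartment cells (all FALSE when the
#' study carries no population dictionary or the sample has no labels).
#' @noRd
neutrophil_mask <- function(study, ct) {
  comp <- compartment_of(study)
  if (is.null(comp) || is.null(ct$population_labels)) {
    return(rep(FALSE, nrow(ct$values)))
  }
  comp[ct$population_labels] == "neutrophil" & !is.na(comp[ct$population_labels])
}
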