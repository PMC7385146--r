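#' Read one sample's event table from CSV
#'
#' The CSV must carry a header row naming the markers; a `population` column,
#' when present, is read as ground-truth per-cell labels, never as a marker.
#' Columns are reordered to the canonical panel order on read, so results do
#' not depend on on-disk column order.
#'
#' @param path CSV file path.
#' @param panel a [marker_panel()] the file must cover.
#' @param sample_id sample identifier; defaults to the file name sans
#'   extension.
#' @param scale intensity scale the stored values are on.
#' @return A [cell_table()].
#' @export
read_sample <- function(path, panel, sample_id = NULL,
                        scale = c("arcsinh", "raw")) {
  panel <- check_panel(panel)
  scale <- match.arg(scale)
  if (!file.exists(path)) cb_stop(paste0("cannot read '", path, "'"), "cytoboot_io_error")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  labels <- NULL
  if ("population" %in% names(df)) {
    labels <- as.character(df[["population"]])
    df[["population"]] <- NULL
  }
  missing <- setdiff(panel$marker, names(df))
  if (length(missing) > 0L) {
    cb_stop(paste0("file '", basename(path), "' is missing panel marker(s): ",
                   paste(missing, collapse = ", ")), "cytoboot_format_error")
  }
  values <- as.matrix(df[, panel$marker, drop = FALSE])
  storage.mode(values) <- "double"
  cell_table(values, panel, sample_id, scale = scale, population_labels = labels)
}

#' Write one sample's event table to CSV
#'
#' Inverse of [read_sample()]: markers in panel order plus a trailing
#' `population` column when labels are present.
#'
#' @param ct a [cell_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(ct, path) {
  df <- as.data.frame(ct$values)
  if (!is.null(ct$population_labels)) df$population <- ct$population_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a whole study to a directory
#'
#' Produces one CSV per sample, a `manifest.csv` (sample_id, patient_id, arm,
#' timepoint, path), a `panel.yaml`, and — when the study carries a
#' population dictionary — a `populations.csv`.
#'
#' @param study a `cytoboot_study`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(study$metadata))
  for (i in seq_len(nrow(study$metadata))) {
    id <- study$metadata$sample_id[i]
    paths[i] <- file.path(dir, paste0(id, ".csv"))
    write_sample(study$samples[[id]], paths[i])
  }
  manifest <- cbind(study$metadata, path = basename(paths))
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  write_panel(study$panel, file.path(dir, "panel.yaml"))
  writeLines(study$timepoints, file.path(dir, "timepoints.txt"))
  if (!is.null(study$populations)) {
    utils::write.csv(study$populations, file.path(dir, "populations.csv"),
                     row.names = FALSE)
  }
  invisible(manifest_path)
}

#' Assemble a study from a samples manifest
#'
#' @param manifest path to a manifest CSV with columns `sample_id`,
#'   `patient_id`, `arm`, `timepoint`, `path` (paths resolved relative to the
#'   manifest's directory unless absolute).
#' @param panel a [marker_panel()] or path to a panel YAML.
#' @param timepoints ordered timepoint labels, baseline first. Defaults to a
#'   `timepoints.txt` next to the manifest when present, else the order of
#'   first appearance in the manifest.
#' @param scale intensity scale of the stored values.
#' @return A `cytoboot_study`.
#' @export
assemble_study <- function(manifest, panel, timepoints = NULL,
                           scale = c("arcsinh", "raw")) {
  scale <- match.arg(scale)
  if (is.character(panel) && length(panel) == 1L && file.exists(panel)) {
    panel <- read_panel(panel)
  }
  panel <- check_panel(panel)
  mdir <- dirname(manifest)
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "arm", "timepoint", "path")
  if (!all(req %in% names(m))) {
    cb_stop(paste0("manifest must have columns: ", paste(req, collapse = ", ")),
            "cytoboot_consistency_error")
  }
  if (nrow(m) == 0L) cb_stop("manifest lists no samples", "cytoboot_consistency_error")
  if (is.null(timepoints)) {
    tp_file <- file.path(mdir, "timepoints.txt")
    timepoints <- if (file.exists(tp_file)) readLines(tp_file) else unique(m$timepoint)
  }
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path, file.path(mdir, m$path))
  samples <- lapply(seq_len(nrow(m)), function(i) {
    read_sample(paths[i], panel, sample_id = m$sample_id[i], scale = scale)
  })
  populations <- NULL
  pop_file <- file.path(mdir, "populations.csv")
  if (file.exists(pop_file)) {
    populations <- utils::read.csv(pop_file, stringsAsFactors = FALSE)
  }
  study(samples, m[, req[1:4]], timepoints, populations = populations)
}
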