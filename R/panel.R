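#' Define a marker panel
#'
#' A panel assigns every measured marker a role: `phenotypic` markers are
#' surface proteins that define cell identity and drive clustering;
#' `functional` markers are intracellular (mostly phospho-) proteins that
#' report signaling activity and drive the response features.
#'
#' @param phenotypic character vector of phenotypic marker names.
#' @param functional character vector of functional marker names.
#' @return A data.frame with columns `marker` and `role`, class
#'   `"cytoboot_panel"`. Column order is canonical: phenotypic first, then
#'   functional, in the order given.
#' @examples
#' marker_panel(c("CD45", "CD3"), c("pSTAT3", "pCREB"))
#' @export
marker_panel <- function(phenotypic, functional) {
  phenotypic <- as.character(phenotypic)
  functional <- as.character(functional)
  markers <- c(phenotypic, functional)
  if (anyDuplicated(markers)) {
    cb_stop(paste0("duplicate marker names in panel: ",
                   paste(unique(markers[duplicated(markers)]), collapse = ", ")),
            "cytoboot_config_error")
  }
  if (length(markers) == 0L) cb_stop("panel has no markers", "cytoboot_config_error")
  out <- data.frame(
    marker = markers,
    role = rep(c("phenotypic", "functional"),
               c(length(phenotypic), length(functional))),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cytoboot_panel", "data.frame")
  out
}

#' Default 26 + 11 marker panel
#'
#' Twenty-six phenotypic surface markers covering the major innate and
#' adaptive immune lineages, plus eleven intracellular functional markers
#' (JAK/STAT, MAPK/CREB and NF-kB pathway members and total IkBa).
#'
#' @return A `"cytoboot_panel"` data.frame with 37 markers.
#' @export
default_panel <- function() {
  marker_panel(
    phenotypic = c("CD45", "CD66", "CD3", "CD4", "CD8a", "CD19", "CD20",
                   "CD56", "CD16", "CD14", "CD11b", "CD11c", "HLADR",
                   "CD123", "CD33", "CD61", "CD235ab", "CD45RA", "CD27",
                   "CD25", "FoxP3", "Tbet", "TCRgd", "CD7", "CD38", "CD24"),
    functional = c("pSTAT1", "pSTAT3", "pSTAT5", "pSTAT6", "pNFkB",
                   "pMAPKAPK2", "pP38", "prpS6", "pERK12", "pCREB", "IkBa")
  )
}

panel_markers <- function(panel, role = NULL) {
  if (is.null(role)) panel$marker else panel$marker[panel$role == role]
}

check_panel <- function(panel) {
  if (!inherits(panel, "cytoboot_panel")) {
    if (is.data.frame(panel) && all(c("marker", "role") %in% names(panel))) {
      class(panel) <- c("cytoboot_panel", "data.frame")
    } else {
      cb_stop("`panel` must be a cytoboot_panel (see marker_panel())",
              "cytoboot_config_error")
    }
  }
  if (!all(panel$role %in% c("phenotypic", "functional"))) {
    cb_stop("panel roles must be 'phenotypic' or 'functional'",
            "cytoboot_config_error")
  }
  panel
}

#' Write / read a panel definition as YAML
#'
#' The on-disk format maps each marker name to its role.
#'
#' @param panel a `"cytoboot_panel"`.
#' @param path file path.
#' @return `read_panel` returns a `"cytoboot_panel"`; `write_panel` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- check_panel(panel)
  yaml::write_yaml(stats::setNames(as.list(panel$role), panel$marker), path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  spec <- yaml::read_yaml(path)
  role <- unlist(spec)
  marker_panel(names(role)[role == "phenotypic"], names(role)[role == "functional"])
}

#' @export
print.cytoboot_panel <- function(x, ...) {
  cat(sprintf("Marker panel: %d phenotypic + %d functional markers\n",
              sum(x$role == "phenotypic"), sum(x$role == "functional")))
  cat("  phenotypic:", paste(panel_markers(x, "phenotypic"), collapse = ", "), "\n")
  cat("  functional:", paste(panel_markers(x, "functional"), collapse = ", "), "\n")
  invisible(x)
}
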