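#' Specify a synthetic cell population
#'
#' Each population is a Gaussian mixture component on the arcsinh scale:
#' phenotypic markers get a per-marker mean and spread defining the
#' population's surface phenotype, functional markers a baseline mean and
#' spread defining its resting signaling tone.
#'
#' @param name population label (stored as ground truth per cell).
#' @param compartment `"innate"`, `"adaptive"` or `"neutrophil"`. The
#'   neutrophil compartment is excluded from metaclustering and reported as a
#'   percentage of all cells rather than of mononuclear cells.
#' @param phenotype_centers named numeric vector over phenotypic markers
#'   (arcsinh units).
#' @param phenotype_spread per-marker SD; scalar recycled or named vector.
#' @param functional_baseline named numeric over functional markers (arcsinh
#'   units).
#' @param functional_spread per-functional-marker SD; scalar or named vector.
#' @param base_fraction expected fraction of a sample's cells, in \[0, 1\].
#' @return A `"population_spec"` list.
#' @export
population_spec <- function(name, compartment = c("innate", "adaptive", "neutrophil"),
                            phenotype_centers, phenotype_spread = 0.4,
                            functional_baseline, functional_spread = 0.5,
                            base_fraction) {
  compartment <- match.arg(compartment)
  if (!is.numeric(base_fraction) || base_fraction < 0 || base_fraction > 1) {
    cb_stop("base_fraction must be in [0, 1]", "cytoboot_config_error")
  }
  if (any(phenotype_spread <= 0) || any(functional_spread <= 0)) {
    cb_stop("spreads must be > 0", "cytoboot_config_error")
  }
  structure(list(name = as.character(name), compartment = compartment,
                 phenotype_centers = phenotype_centers,
                 phenotype_spread = phenotype_spread,
                 functional_baseline = functional_baseline,
                 functional_spread = functional_spread,
                 base_fraction = base_fraction),
            class = "population_spec")
}

#' Specify a plantable arm-specific effect
#'
#' An effect modifies one population in one arm at chosen post-baseline
#' timepoints: its expected sample fraction is multiplied by
#' `frequency_multiplier` (then all fractions are renormalized), and its
#' functional-marker means are shifted additively by `signaling_shift`.
#'
#' @param population target population name.
#' @param arm target arm label.
#' @param timepoints post-baseline timepoints the effect applies at.
#' @param frequency_multiplier positive scalar on the base fraction.
#' @param signaling_shift named numeric of additive shifts (arcsinh units)
#'   on functional markers; markers not named are untouched.
#' @return An `"effect_spec"` list.
#' @export
effect_spec <- function(population, arm, timepoints,
                        frequency_multiplier = 1, signaling_shift = numeric(0)) {
  if (!is.numeric(frequency_multiplier) || frequency_multiplier <= 0) {
    cb_stop("frequency_multiplier must be > 0", "cytoboot_config_error")
  }
  structure(list(population = as.character(population), arm = as.character(arm),
                 timepoints = as.character(timepoints),
                 frequency_multiplier = frequency_multiplier,
                 signaling_shift = signaling_shift),
            class = "effect_spec")
}

## Build a full phenotype-center vector: low background everywhere, chosen
## markers high. Values in arcsinh units typical of CyTOF data.
pheno_signature <- function(panel, high, low = 0.3) {
  ph <- panel_markers(panel, "phenotypic")
  centers <- stats::setNames(rep(low, length(ph)), ph)
  hit <- intersect(names(high), ph)
  centers[hit] <- high[hit]
  centers
}

fun_baseline <- function(panel, overrides = c()) {
  fm <- panel_markers(panel, "functional")
  base <- stats::setNames(rep(0.8, length(fm)), fm)
  base[intersect(names(overrides), fm)] <- overrides[intersect(names(overrides), fm)]
  base
}

#' Default synthetic immune populations
#'
#' Twelve populations spanning the major innate (neutrophils, classical /
#' non-classical monocytes, mDCs, pDCs, NK cells) and adaptive (naive and
#' memory CD4 T, CD8 T, Tregs, B cells, gd T) lineages, with canonical
#' surface-marker signatures on the [default_panel()] and base fractions
#' summing to 1.
#'
#' @param panel the marker panel the centers are defined over.
#' @return List of [population_spec()]s.
#' @export
default_populations <- function(panel = default_panel()) {
  P <- function(...) pheno_signature(panel, c(...))
  list(
    population_spec("Neutrophil", "neutrophil",
                    P("CD45" = 2.2, "CD66" = 4.2, "CD11b" = 3.6, "CD16" = 3.2),
                    functional_baseline = fun_baseline(panel, c(pNFkB = 1.1)),
                    base_fraction = 0.15),
    population_spec("cMC", "innate",
                    P("CD45" = 4, "CD14" = 4, "CD33" = 3.6, "CD11b" = 3.4, "HLADR" = 3),
                    functional_baseline = fun_baseline(panel, c(pCREB = 1.4, pMAPKAPK2 = 1.2)),
                    base_fraction = 0.12),
    population_spec("ncMC", "innate",
                    P("CD45" = 4, "CD16" = 3.8, "CD33" = 3, "CD11c" = 3.2, "HLADR" = 3),
                    functional_baseline = fun_baseline(panel, c(pCREB = 1.2)),
                    base_fraction = 0.04),
    population_spec("mDC", "innate",
                    P("CD45" = 4, "CD11c" = 4, "HLADR" = 3.8, "CD33" = 2.8),
                    functional_baseline = fun_baseline(panel),
                    base_fraction = 0.03),
    population_spec("pDC", "innate",
                    P("CD45" = 4, "CD123" = 4, "HLADR" = 3.4),
                    functional_baseline = fun_baseline(panel),
                    base_fraction = 0.02),
    population_spec("NK", "innate",
                    P("CD45" = 4, "CD56" = 3.6, "CD16" = 3.4, "CD7" = 3.2),
                    functional_baseline = fun_baseline(panel, c(pSTAT1 = 1.0)),
                    base_fraction = 0.08),
    population_spec("CD4Tnaive", "adaptive",
                    P("CD45" = 4, "CD3" = 4, "CD4" = 3.8, "CD45RA" = 3.6, "CD27" = 3.2, "CD7" = 3),
                    functional_baseline = fun_baseline(panel),
                    base_fraction = 0.16),
    population_spec("CD4Tmem", "adaptive",
                    P("CD45" = 4, "CD3" = 4, "CD4" = 3.8, "CD27" = 3, "CD7" = 3),
                    functional_baseline = fun_baseline(panel, c(pSTAT3 = 1.0)),
                    base_fraction = 0.14),
    population_spec("CD8T", "adaptive",
                    P("CD45" = 4, "CD3" = 4, "CD8a" = 3.8, "CD7" = 3.2, "CD45RA" = 2.4),
                    functional_baseline = fun_baseline(panel),
                    base_fraction = 0.12),
    population_spec("Treg", "adaptive",
                    P("CD45" = 4, "CD3" = 4, "CD4" = 3.6, "CD25" = 3.4, "FoxP3" = 3.2),
                    functional_baseline = fun_baseline(panel, c(pSTAT5 = 1.2)),
                    base_fraction = 0.03),
    population_spec("Bcell", "adaptive",
                    P("CD45" = 4, "CD19" = 3.8, "CD20" = 3.8, "HLADR" = 3.4, "CD24" = 3),
                    functional_baseline = fun_baseline(panel, c(pSTAT6 = 1.0)),
                    base_fraction = 0.09),
    population_spec("gdT", "adaptive",
                    P("CD45" = 4, "CD3" = 4, "TCRgd" = 3.8, "CD7" = 3.2),
                    functional_baseline = fun_baseline(panel),
                    base_fraction = 0.02)
  )
}

#' Default surgery response profile
#'
#' Additive, arm-independent shifts of functional-marker means at
#' post-baseline timepoints, emulating the stereotypical mobilization after
#' major surgery: a JAK/STAT and CREB/MAPK surge in innate cells peaking
#' around 1-24 h and resolved by 2 weeks, and a smaller STAT surge in
#' adaptive cells. Structured as
#' `list(population = list(marker = c(timepoint = shift, ...)))`.
#'
#' @param populations list of [population_spec()]s.
#' @param timepoints study timepoints (baseline first).
#' @return Nested list usable as the `surgery_response` field of
#'   [study_config()].
#' @export
default_surgery_response <- function(populations = default_populations(),
                                     timepoints = c("baseline", "1h", "6h", "24h", "48h", "2wk")) {
  post <- setdiff(timepoints, timepoints[1L])
  shape <- function(peak) {
    prof <- stats::setNames(rep(0, length(post)), post)
    n <- length(post)
    ramp <- c(0.7, 1, 0.6, 0.3, 0)[seq_len(min(5, n))]
    prof[seq_along(ramp)] <- peak * ramp
    prof
  }
  out <- list()
  for (p in populations) {
    if (p$compartment %in% c("innate", "neutrophil")) {
      out[[p$name]] <- list(pSTAT3 = shape(0.9), pCREB = shape(0.7),
                            pMAPKAPK2 = shape(0.5), pNFkB = shape(0.4))
    } else {
      out[[p$name]] <- list(pSTAT3 = shape(0.4), pSTAT5 = shape(0.5))
    }
  }
  out
}

#' Configure a synthetic two-arm longitudinal study
#'
#' Defaults emulate the trial design the pipeline targets: two arms of 30
#' (control) and 28 (treatment) patients, six timepoints (baseline then 1 h,
#' 6 h, 24 h, 48 h, 2 wk), a 26 + 11 marker panel, twelve populations
#' including one neutrophil population, a shared surgery-response profile in
#' both arms, and no arm-specific effects (plant those with [effect_spec()]).
#'
#' @param n_patients_per_arm integer (same size both arms) or length-2 named
#'   vector of per-arm patient counts; each arm needs >= 2 patients.
#' @param timepoints ordered labels, first is baseline.
#' @param cells_per_sample single cell count, or length-2 range from which
#'   per-sample counts are drawn uniformly.
#' @param panel a [marker_panel()].
#' @param populations list of [population_spec()]s; base fractions must sum
#'   to 1.
#' @param effects list of [effect_spec()]s planting arm-specific effects.
#' @param surgery_response nested list of both-arm post-baseline shifts, see
#'   [default_surgery_response()].
#' @param patient_effect_sd SD of a per-patient random intercept added to all
#'   functional-marker means (arcsinh units); gives each patient a stable
#'   signaling tone that baseline subtraction removes.
#' @param seed master seed; identical configs generate bit-identical studies.
#' @return A `"study_config"` list.
#' @export
study_config <- function(n_patients_per_arm = c(control = 30, treatment = 28),
                         timepoints = c("baseline", "1h", "6h", "24h", "48h", "2wk"),
                         cells_per_sample = 5000,
                         panel = default_panel(),
                         populations = default_populations(panel),
                         effects = list(),
                         surgery_response = default_surgery_response(populations, timepoints),
                         patient_effect_sd = 0.1,
                         seed = 1L) {
  if (length(n_patients_per_arm) == 1L) {
    n_patients_per_arm <- c(control = n_patients_per_arm, treatment = n_patients_per_arm)
  }
  if (is.null(names(n_patients_per_arm)) || any(names(n_patients_per_arm) == "")) {
    names(n_patients_per_arm) <- c("control", "treatment")
  }
  cfg <- structure(
    list(n_patients_per_arm = n_patients_per_arm, timepoints = as.character(timepoints),
         cells_per_sample = cells_per_sample, panel = check_panel(panel),
         populations = populations, effects = effects,
         surgery_response = surgery_response,
         patient_effect_sd = patient_effect_sd, seed = as.integer(seed)),
    class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  if (any(cfg$n_patients_per_arm < 2)) {
    cb_stop("each arm needs at least 2 patients", "cytoboot_config_error")
  }
  if (length(cfg$timepoints) < 2L) cb_stop("need >= 2 timepoints", "cytoboot_config_error")
  if (any(cfg$cells_per_sample <= 0) || length(cfg$cells_per_sample) > 2L) {
    cb_stop("cells_per_sample must be a positive count or range", "cytoboot_config_error")
  }
  fracs <- vapply(cfg$populations, function(p) p$base_fraction, numeric(1))
  if (abs(sum(fracs) - 1) > 1e-9) {
    cb_stop(sprintf("population base_fractions must sum to 1 (got %.6f)", sum(fracs)),
            "cytoboot_config_error")
  }
  pop_names <- vapply(cfg$populations, function(p) p$name, character(1))
  if (anyDuplicated(pop_names)) cb_stop("duplicate population names", "cytoboot_config_error")
  baseline <- cfg$timepoints[1L]
  for (e in cfg$effects) {
    if (!e$population %in% pop_names) {
      cb_stop(paste0("effect targets unknown population '", e$population, "'"),
              "cytoboot_config_error")
    }
    if (!e$arm %in% names(cfg$n_patients_per_arm)) {
      cb_stop(paste0("effect targets unknown arm '", e$arm, "'"), "cytoboot_config_error")
    }
    if (!all(e$timepoints %in% cfg$timepoints)) {
      cb_stop("effect targets unknown timepoint(s)", "cytoboot_config_error")
    }
    if (baseline %in% e$timepoints) {
      cb_stop("effects cannot target the baseline timepoint", "cytoboot_config_error")
    }
    fm <- panel_markers(cfg$panel, "functional")
    if (length(e$signaling_shift) && !all(names(e$signaling_shift) %in% fm)) {
      cb_stop("signaling_shift names must be functional markers", "cytoboot_config_error")
    }
  }
  invisible(cfg)
}

## Expand a possibly-scalar / partially-named spread to a full named vector.
full_vector <- function(x, markers, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(x, length(markers)), markers))
  }
  if (!all(markers %in% names(x))) {
    cb_stop(paste0(what, " must name every marker"), "cytoboot_config_error")
  }
  x[markers]
}

#' Generate a synthetic study
#'
#' Draws one [cell_table()] per (patient, timepoint). Per sample, population
#' counts come from a multinomial over the (effect-adjusted, renormalized)
#' base fractions; marker values are independent Gaussians per population on
#' the arcsinh scale. The surgery response applies to both arms at
#' post-baseline timepoints; [effect_spec()]s apply only to their target arm
#' and timepoints. Ground-truth population labels are stored per cell. All
#' randomness derives from `config$seed` via per-patient and per-sample
#' seeds, so generation is byte-identical for identical configs and
#' independent of evaluation order.
#'
#' @param config a [study_config()].
#' @return A `cytoboot_study`.
#' @examples
#' cfg <- study_config(n_patients_per_arm = 2, timepoints = c("baseline", "6h"),
#'                     cells_per_sample = 200, seed = 7)
#' st <- generate_study(cfg)
#' st
#' @export
generate_study <- function(config) {
  validate_study_config(config)
  panel <- config$panel
  ph <- panel_markers(panel, "phenotypic")
  fm <- panel_markers(panel, "functional")
  pops <- config$populations
  pop_names <- vapply(pops, function(p) p$name, character(1))
  base_fracs <- vapply(pops, function(p) p$base_fraction, numeric(1))
  names(base_fracs) <- pop_names
  baseline <- config$timepoints[1L]
  arms <- names(config$n_patients_per_arm)

  ## Pre-expand per-population parameter vectors once.
  centers <- lapply(pops, function(p) full_vector(p$phenotype_centers, ph, "phenotype_centers"))
  spreads <- lapply(pops, function(p) full_vector(p$phenotype_spread, ph, "phenotype_spread"))
  fbase <- lapply(pops, function(p) full_vector(p$functional_baseline, fm, "functional_baseline"))
  fspread <- lapply(pops, function(p) full_vector(p$functional_spread, fm, "functional_spread"))

  surgery_shift <- function(pop, tp) {
    prof <- config$surgery_response[[pop]]
    out <- stats::setNames(rep(0, length(fm)), fm)
    if (is.null(prof) || tp == baseline) return(out)
    for (mk in names(prof)) {
      v <- prof[[mk]]
      if (mk %in% fm && tp %in% names(v)) out[mk] <- out[mk] + v[[tp]]
    }
    out
  }

  meta <- list()
  samples <- list()
  for (arm in arms) {
    for (i in seq_len(config$n_patients_per_arm[[arm]])) {
      pid <- sprintf("%s_%02d", arm, i)
      pat_offset <- with_seed(derive_seed(config$seed, "patient", pid),
                              stats::rnorm(length(fm), 0, config$patient_effect_sd))
      names(pat_offset) <- fm
      for (tp in config$timepoints) {
        sid <- paste(pid, tp, sep = "_")
        ct <- with_seed(derive_seed(config$seed, "sample", pid, tp), {
          n_cells <- if (length(config$cells_per_sample) == 2L) {
            sample(seq(config$cells_per_sample[1L], config$cells_per_sample[2L]), 1L)
          } else as.integer(config$cells_per_sample)
          fracs <- base_fracs
          shifts <- stats::setNames(rep(0, length(fm)), fm)
          shift_by_pop <- stats::setNames(vector("list", length(pops)), pop_names)
          for (e in config$effects) {
            if (e$arm == arm && tp %in% e$timepoints) {
              fracs[e$population] <- fracs[e$population] * e$frequency_multiplier
              if (length(e$signaling_shift)) {
                s <- shift_by_pop[[e$population]] %||% stats::setNames(rep(0, length(fm)), fm)
                s[names(e$signaling_shift)] <- s[names(e$signaling_shift)] + e$signaling_shift
                shift_by_pop[[e$population]] <- s
              }
            }
          }
          fracs <- fracs / sum(fracs)
          counts <- as.vector(stats::rmultinom(1L, n_cells, fracs))
          blocks <- vector("list", length(pops))
          for (k in seq_along(pops)) {
            ck <- counts[k]
            if (ck == 0L) next
            mu_f <- fbase[[k]] + pat_offset + surgery_shift(pop_names[k], tp) +
              (shift_by_pop[[pop_names[k]]] %||% 0)
            phen <- t(matrix(stats::rnorm(length(ph) * ck, mean = centers[[k]],
                                          sd = spreads[[k]]), nrow = length(ph)))
            func <- t(matrix(stats::rnorm(length(fm) * ck, mean = mu_f,
                                          sd = fspread[[k]]), nrow = length(fm)))
            blocks[[k]] <- cbind(phen, func)
          }
          values <- do.call(rbind, blocks[counts > 0])
          colnames(values) <- c(ph, fm)
          labels <- rep(pop_names, counts)
          cell_table(values, panel, sid, scale = "arcsinh", population_labels = labels)
        })
        samples[[sid]] <- ct
        meta[[sid]] <- data.frame(sample_id = sid, patient_id = pid, arm = arm,
                                  timepoint = tp, stringsAsFactors = FALSE)
      }
    }
  }
  populations <- data.frame(
    population = pop_names,
    compartment = vapply(pops, function(p) p$compartment, character(1)),
    stringsAsFactors = FALSE
  )
  study(samples, do.call(rbind, meta), config$timepoints, populations = populations)
}
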