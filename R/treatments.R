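#' Treatment specification
#'
#' Describes one treatment class: its herbicide name, mode-of-action (MOA)
#' group, site-of-action (SOA) target, field dose, and the spectral effect
#' bands the synthetic generator injects for it. Effect bands are
#' multiplicative Gaussian perturbations of the leaf reflectance, each with a
#' centre wavelength, a Gaussian width (sd, nm), a signed relative amplitude,
#' an onset day and an optional per-day centre drift (nm/day) that emulates
#' the temporal evolution of stress symptoms.
#'
#' @param name Treatment label (e.g. `"Atrazine"`, `"UTC"` for the untreated
#'   control).
#' @param moa_group MOA group label.
#' @param soa_target SOA target label (the classification label of interest).
#' @param dose_g_ha Applied dose in g/ha (metadata only; never enters the
#'   simulation).
#' @param effect_bands Data frame with columns `center_nm`, `width_nm`,
#'   `amplitude`, `onset_day` and optionally `drift_nm_per_day`. The untreated
#'   control must have zero rows.
#' @param severity_growth Per-day multiplier applied to effect amplitudes
#'   after onset (>= 1 means symptoms intensify).
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(name, moa_group, soa_target, dose_g_ha = NA_real_,
                           effect_bands = empty_effect_bands(),
                           severity_growth = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  effect_bands <- as.data.frame(effect_bands)
  if (nrow(effect_bands) > 0) {
    needed <- c("center_nm", "width_nm", "amplitude", "onset_day")
    missing <- setdiff(needed, names(effect_bands))
    if (length(missing) > 0) {
      stop("effect_bands lacks columns: ", paste(missing, collapse = ", "))
    }
    if (is.null(effect_bands$drift_nm_per_day)) {
      effect_bands$drift_nm_per_day <- 0
    }
    if (!all(is.finite(as.matrix(effect_bands)))) {
      stop("effect_bands values must be finite")
    }
    if (any(effect_bands$width_nm <= 0)) stop("effect widths must be > 0")
  }
  structure(
    list(name = name, moa_group = moa_group, soa_target = soa_target,
         dose_g_ha = dose_g_ha, effect_bands = effect_bands,
         severity_growth = severity_growth),
    class = "treatment_spec"
  )
}

#' @rdname treatment_spec
#' @export
empty_effect_bands <- function() {
  data.frame(center_nm = numeric(0), width_nm = numeric(0),
             amplitude = numeric(0), onset_day = numeric(0),
             drift_nm_per_day = numeric(0))
}

effect_band <- function(center_nm, width_nm, amplitude, onset_day = 0,
                        drift_nm_per_day = 0) {
  data.frame(center_nm = center_nm, width_nm = width_nm,
             amplitude = amplitude, onset_day = onset_day,
             drift_nm_per_day = drift_nm_per_day)
}

#' Default study treatments
#'
#' The nine-class vocabulary used throughout: an untreated control (UTC) plus
#' eight herbicides spanning four MOA groups, each with a unique SOA target.
#' Doses are the study's field rates. Effect bands are synthetic-generator
#' defaults: each herbicide perturbs reflectance at a distinct pair of
#' centres (visible enhancements, NIR depressions), so classes are separable
#' by construction and feature-selection recovery is checkable against known
#' centres.
#'
#' @return Named list of [treatment_spec()] objects in canonical order
#'   (control first).
#' @export
default_treatments <- function() {
  specs <- list(
    treatment_spec("UTC", "Control", "Untreated"),
    treatment_spec("Atrazine", "Photosynthesis inhibition", "PS II inhibition",
                   dose_g_ha = 62.5,
                   effect_bands = rbind(
                     effect_band(700, 10, 0.32, onset_day = 0, drift_nm_per_day = 5),
                     effect_band(545, 12, 0.12, onset_day = 0)),
                   severity_growth = 1.2),
    treatment_spec("Dinoseb", "Photosynthesis inhibition", "Uncoupler",
                   dose_g_ha = 125,
                   effect_bands = rbind(
                     effect_band(716, 9, 0.28, onset_day = 0, drift_nm_per_day = -5),
                     effect_band(668, 8, 0.14, onset_day = 0)),
                   severity_growth = 1.25),
    treatment_spec("Flumioxazin", "Cell membrane disrupter", "PPO enzyme",
                   dose_g_ha = 1.56,
                   effect_bands = rbind(
                     effect_band(920, 16, -0.3, onset_day = 0, drift_nm_per_day = 6),
                     effect_band(660, 10, 0.1, onset_day = 0)),
                   severity_growth = 1.2),
    treatment_spec("Paraquat", "Cell membrane disrupter",
                   "PS I electron diversion", dose_g_ha = 3.9,
                   effect_bands = rbind(
                     effect_band(752, 12, -0.3, onset_day = 0, drift_nm_per_day = 6),
                     effect_band(500, 10, 0.12, onset_day = 0)),
                   severity_growth = 1.3),
    treatment_spec("Glyphosate", "Amino acid synthesis inhibition",
                   "EPSPS synthase", dose_g_ha = 15.6,
                   effect_bands = rbind(
                     effect_band(582, 10, 0.26, onset_day = 0, drift_nm_per_day = 4),
                     effect_band(900, 16, -0.1, onset_day = 0)),
                   severity_growth = 1.15),
    treatment_spec("Glufosinate", "Amino acid synthesis inhibition",
                   "Glutamine synthase", dose_g_ha = 62.5,
                   effect_bands = rbind(
                     effect_band(562, 10, 0.26, onset_day = 0, drift_nm_per_day = -4),
                     effect_band(726, 10, 0.1, onset_day = 0)),
                   severity_growth = 1.15),
    treatment_spec("Chlorimuron", "Amino acid synthesis inhibition",
                   "ALS enzyme", dose_g_ha = 25,
                   effect_bands = rbind(
                     effect_band(540, 10, 0.26, onset_day = 0, drift_nm_per_day = 4),
                     effect_band(840, 14, -0.1, onset_day = 0)),
                   severity_growth = 1.15),
    treatment_spec("Indaziflam", "Cellulose biosynthesis inhibitor",
                   "Cellulose synthesis", dose_g_ha = 62.5,
                   effect_bands = rbind(
                     effect_band(862, 14, -0.3, onset_day = 0, drift_nm_per_day = 6),
                     effect_band(610, 10, 0.12, onset_day = 0)),
                   severity_growth = 1.2)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Canonical class order
#'
#' Control first, then the herbicides in study-table order. All confusion
#' matrices, soft-voting tie-breaks and heatmaps use this ordering.
#'
#' @return Character vector of the nine treatment names.
#' @export
canonical_classes <- function() {
  c("UTC", "Atrazine", "Dinoseb", "Flumioxazin", "Paraquat",
    "Glyphosate", "Glufosinate", "Chlorimuron", "Indaziflam")
}
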