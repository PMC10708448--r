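#' Study configuration
#'
#' Shape and noise model of a full multi-day, multi-round experiment. The
#' defaults mirror the study design: 8 herbicides at 16 samples each plus 32
#' untreated controls per round, two rounds (320 samples total), imaged on 7
#' daily time points, with 5 severely damaged outlier plants appearing at
#' 2 DAT.
#'
#' @param treatments Named list of [treatment_spec()] (first entry is the
#'   control).
#' @param samples_per_herbicide Samples per herbicide per round.
#' @param control_samples Control samples per round.
#' @param rounds Number of experimental rounds.
#' @param days Strictly increasing vector of DAT time points.
#' @param outlier_count,outlier_day Number of plants turning necrotic and the
#'   day necrosis appears.
#' @param noise_sd Per-band spectral noise sd (reflectance fraction).
#' @param scatter_slope_sd,scatter_offset_sd Per-spectrum multiplicative /
#'   additive scatter sd (what MSC is meant to remove).
#' @param day_curve_amplitude Amplitude of a smooth day-specific spectral
#'   perturbation common to all samples of a day (illumination/physiology
#'   drift between acquisition days; drives the day-to-day validation gap).
#' @param amplitude_scale Global multiplier on treatment effect amplitudes.
#' @param wavelengths Generation grid.
#' @param crop Wavelength crop applied to the emitted table (`NULL` to keep
#'   the full grid).
#' @param smooth Apply Savitzky-Golay smoothing (order 1, window 5) at
#'   extraction, as the imaging pipeline does.
#' @param seed Root seed; all study randomness derives from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(treatments = default_treatments(),
                         samples_per_herbicide = 16, control_samples = 32,
                         rounds = 2, days = 1:7,
                         outlier_count = 5, outlier_day = 2,
                         noise_sd = 0.004, scatter_slope_sd = 0.05,
                         scatter_offset_sd = 0.01,
                         day_curve_amplitude = 0.025,
                         amplitude_scale = 1,
                         wavelengths = default_grid(),
                         crop = c(460, 975), smooth = TRUE, seed = 1) {
  stopifnot(samples_per_herbicide >= 0, control_samples >= 0, rounds >= 0,
            outlier_count >= 0, noise_sd >= 0)
  if (length(days) > 1 && any(diff(days) <= 0)) {
    stop("days must be strictly increasing")
  }
  if (!all(vapply(treatments, inherits, logical(1), "treatment_spec"))) {
    stop("treatments must be a list of treatment_spec objects")
  }
  tnames <- vapply(treatments, `[[`, character(1), "name")
  unknown <- setdiff(tnames, canonical_classes())
  if (length(unknown) > 0) {
    stop("unknown treatment name(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(treatments = treatments,
                 samples_per_herbicide = samples_per_herbicide,
                 control_samples = control_samples, rounds = rounds,
                 days = days, outlier_count = outlier_count,
                 outlier_day = outlier_day, noise_sd = noise_sd,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 day_curve_amplitude = day_curve_amplitude,
                 amplitude_scale = amplitude_scale,
                 wavelengths = wavelengths, crop = crop, smooth = smooth,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a full synthetic study
#'
#' Simulates extracted mean spectra for every sample, round and day of the
#' configured experiment, with known ground truth. Each plant has a
#' persistent biological identity (its own slightly perturbed leaf
#' endmember); per day it receives its treatment's deterministic effect, a
#' smooth day-specific drift curve, per-spectrum affine scatter and additive
#' noise, then the pipeline's crop and Savitzky-Golay smoothing. Flagged
#' outlier plants become near-zero-reflectance (necrotic) from
#' `outlier_day` onward.
#'
#' All randomness flows from `cfg$seed`: the generator seeds once and draws
#' in a fixed loop order (days, then rounds, treatments, samples), so the
#' dataset is reproducible bit-for-bit.
#'
#' @param cfg A [study_config()].
#' @return A [spectra_table()] with one row per sample x day. Attribute
#'   `outlier_ids` lists the flagged sample ids.
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  wl <- cfg$wavelengths
  classes <- names(cfg$treatments)
  control <- classes[vapply(cfg$treatments,
                            function(t) nrow(t$effect_bands) == 0,
                            logical(1))][1]
  set.seed(cfg$seed)

  # enumerate samples: persistent identity across days
  samples <- list()
  for (r in seq_len(cfg$rounds)) {
    for (cl in classes) {
      n <- if (!is.na(control) && cl == control) cfg$control_samples
           else cfg$samples_per_herbicide
      if (n == 0) next
      for (s in seq_len(n)) {
        id <- sprintf("R%d_%s_%02d", r, cl, s)
        samples[[length(samples) + 1L]] <- list(id = id, treatment = cl,
                                                round = r)
      }
    }
  }
  n_samples <- length(samples)
  if (n_samples == 0) stop("study configuration yields no samples")

  # per-plant biological variation of the endmember
  plant_base <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    plant_base[[i]] <- leaf_endmember(
      wl,
      vis_base = 0.045 * exp(rnorm(1, 0, 0.06)),
      green_bump = 0.075 * exp(rnorm(1, 0, 0.06)),
      nir_plateau = pmin(0.97, 0.92 + rnorm(1, 0, 0.015)),
      edge_center = 706 + rnorm(1, 0, 0.8))
  }

  # outliers: severely damaged treated plants, flagged from outlier_day on
  treated_idx <- which(vapply(samples, function(s) s$treatment != control,
                              logical(1)))
  n_out <- min(cfg$outlier_count, length(treated_idx))
  outlier_idx <- if (n_out > 0) sort(sample(treated_idx, n_out)) else integer(0)
  outlier_ids <- vapply(samples[outlier_idx], `[[`, character(1), "id")

  # smooth day-specific drift curves shared by all samples of a day
  day_curves <- lapply(seq_along(cfg$days), function(di) {
    co <- rnorm(3, 0, cfg$day_curve_amplitude) * (di - 1)
    u <- (wl - min(wl)) / (max(wl) - min(wl))
    co[1] * sin(pi * u) + co[2] * sin(2 * pi * u) + co[3] * u
  })

  rows <- n_samples * length(cfg$days)
  X <- matrix(NA_real_, rows, length(wl))
  meta <- data.frame(sample_id = character(rows), treatment = character(rows),
                     soa = character(rows), moa_group = character(rows),
                     dat = numeric(rows), round = integer(rows),
                     outlier = logical(rows), stringsAsFactors = FALSE)
  ri <- 0L
  for (di in seq_along(cfg$days)) {
    day <- cfg$days[di]
    for (i in seq_len(n_samples)) {
      s <- samples[[i]]
      spec <- cfg$treatments[[s$treatment]]
      necrotic <- (i %in% outlier_idx) && day >= cfg$outlier_day
      if (necrotic) {
        refl <- rep(0.03, length(wl))
      } else {
        refl <- apply_treatment_effect(plant_base[[i]], spec, day, wl,
                                       amplitude_scale = cfg$amplitude_scale)
        refl <- refl + day_curves[[di]]
      }
      b <- exp(rnorm(1, 0, cfg$scatter_slope_sd))
      a <- rnorm(1, 0, cfg$scatter_offset_sd)
      refl <- b * refl + a + rnorm(length(wl), 0, cfg$noise_sd)
      refl <- pmin(pmax(refl, 1e-4), 1.2)
      ri <- ri + 1L
      X[ri, ] <- refl
      meta$sample_id[ri] <- s$id
      meta$treatment[ri] <- s$treatment
      meta$soa[ri] <- spec$soa_target
      meta$moa_group[ri] <- spec$moa_group
      meta$dat[ri] <- day
      meta$round[ri] <- s$round
      meta$outlier[ri] <- necrotic
    }
  }

  out_wl <- wl
  if (!is.null(cfg$crop)) {
    keep <- crop_indices(wl, cfg$crop)
    X <- X[, keep, drop = FALSE]
    out_wl <- wl[keep]
  }
  if (isTRUE(cfg$smooth)) {
    X <- t(apply(X, 1, savgol_smooth))
  }
  tab <- spectra_table(X, out_wl, meta)
  attr(tab, "outlier_ids") <- outlier_ids
  tab
}

#' Write a study configuration as a YAML-style text file
#'
#' Scalar fields of the configuration as `key: value` lines (treatment
#' details are summarised by name); a human-readable record of how a dataset
#' was generated.
#'
#' @param cfg A [study_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  lines <- c(
    paste0("treatments: [", paste(names(cfg$treatments), collapse = ", "), "]"),
    paste0("samples_per_herbicide: ", cfg$samples_per_herbicide),
    paste0("control_samples: ", cfg$control_samples),
    paste0("rounds: ", cfg$rounds),
    paste0("days: [", paste(cfg$days, collapse = ", "), "]"),
    paste0("outlier_count: ", cfg$outlier_count),
    paste0("outlier_day: ", cfg$outlier_day),
    paste0("noise_sd: ", cfg$noise_sd),
    paste0("scatter_slope_sd: ", cfg$scatter_slope_sd),
    paste0("scatter_offset_sd: ", cfg$scatter_offset_sd),
    paste0("day_curve_amplitude: ", cfg$day_curve_amplitude),
    paste0("amplitude_scale: ", cfg$amplitude_scale),
    paste0("grid: [", min(cfg$wavelengths), ", ", max(cfg$wavelengths), ", ",
           round(cfg$wavelengths[2] - cfg$wavelengths[1], 6), "]"),
    paste0("crop: [", paste(cfg$crop, collapse = ", "), "]"),
    paste0("smooth: ", tolower(as.character(cfg$smooth))),
    paste0("seed: ", cfg$seed)
  )
  writeLines(lines, path)
  invisible(path)
}
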