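#' Default wavelength grid
#'
#' The sensor-like spectral grid: 380-1030 nm at 1.2 nm steps (542 bands).
#' Wide enough that the 460-975 nm analysis crop is always interior.
#'
#' @param start,stop,step Grid limits and step, nm.
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function(start = 380, stop = 1030, step = 1.2) {
  stopifnot(step > 0, stop > start)
  seq(start, stop, by = step)
}

#' Parametric leaf reflectance endmember
#'
#' A vegetation-like reflectance curve: low visible baseline with chlorophyll
#' absorption in blue and red, a green bump near 550 nm, a sigmoidal red edge
#' and a NIR plateau with a mild water dip near 970 nm. Deterministic in its
#' parameters (no randomness).
#'
#' @param wavelengths Monotone increasing grid (nm).
#' @param vis_base Visible-region baseline reflectance.
#' @param green_bump Amplitude of the green reflectance bump at 550 nm.
#' @param nir_plateau NIR plateau reflectance.
#' @param edge_center,edge_scale Red-edge sigmoid centre (nm) and scale (nm);
#'   a small scale gives the steep edge the segmentation operator keys on.
#' @param water_dip Relative depth of the 970 nm water absorption feature.
#' @return Reflectance vector in (0, 1), same length as `wavelengths`.
#' @export
leaf_endmember <- function(wavelengths, vis_base = 0.045, green_bump = 0.075,
                           nir_plateau = 0.92, edge_center = 706,
                           edge_scale = 5, water_dip = 0.05) {
  wl <- as.numeric(wavelengths)
  if (length(wl) == 0) stop("empty wavelength grid")
  if (length(wl) > 1 && any(diff(wl) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  vis <- vis_base +
    green_bump * exp(-(wl - 550)^2 / (2 * 25^2)) -
    0.015 * exp(-(wl - 670)^2 / (2 * 15^2)) -   # red chlorophyll well
    0.015 * exp(-(wl - 440)^2 / (2 * 20^2))     # blue chlorophyll well
  edge <- stats::plogis((wl - edge_center) / edge_scale)
  nir <- nir_plateau * (1 - water_dip * exp(-(wl - 970)^2 / (2 * 18^2)))
  r <- vis * (1 - edge) + nir * edge
  pmin(pmax(r, 1e-4), 1 - 1e-4)
}

#' Apply a treatment's spectral effect
#'
#' Perturbs a base reflectance spectrum with the treatment's effect bands
#' that are active at the given day (`onset_day <= day`). Each band is a
#' multiplicative Gaussian bump/dip whose amplitude grows as
#' `severity_growth^(day - onset_day)` and whose centre drifts by
#' `drift_nm_per_day * (day - onset_day)` nm, emulating intensifying and
#' shifting stress symptoms. Deterministic: all randomness (noise, scatter)
#' is added later by the study generator. Output is clipped to (0, 1).
#'
#' @param base Reflectance spectrum.
#' @param spec A [treatment_spec()].
#' @param day Days after treatment (>= 0).
#' @param wavelengths Grid matching `base`.
#' @param amplitude_scale Global multiplier on all effect amplitudes (used to
#'   study separability as a function of effect size).
#' @return Perturbed reflectance spectrum.
#' @export
apply_treatment_effect <- function(base, spec, day, wavelengths,
                                   amplitude_scale = 1) {
  stopifnot(inherits(spec, "treatment_spec"), day >= 0,
            length(base) == length(wavelengths))
  eb <- spec$effect_bands
  if (nrow(eb) == 0) return(base)
  factor <- rep(1, length(base))
  for (i in seq_len(nrow(eb))) {
    if (eb$onset_day[i] > day) next
    dt <- day - eb$onset_day[i]
    center <- eb$center_nm[i] + eb$drift_nm_per_day[i] * dt
    amp <- amplitude_scale * eb$amplitude[i] * spec$severity_growth^dt
    factor <- factor +
      amp * exp(-(wavelengths - center)^2 / (2 * eb$width_nm[i]^2))
  }
  pmin(pmax(base * factor, 1e-4), 1 - 1e-4)
}

#' Scene configuration
#'
#' Geometry, optics and noise of one synthetic line-scan acquisition. The
#' white reference emulates a flat calibration board of reflectance
#' `background_reflectance` (the plant sits on the same bright flat
#' background), imaged per spatial line so the illumination profile across
#' the sensor line is baked into the white frame. Because vegetation NIR
#' reflectance exceeds the board's, calibrated plant values rise above 1 --
#' exactly the contrast the red-edge threshold relies on.
#'
#' @param height,width Scene size in pixels (rows = scan lines, cols = sensor
#'   line).
#' @param wavelengths Spectral grid, nm.
#' @param plant_fraction Target fraction of pixels covered by the plant
#'   silhouette, in `[0, 1)`.
#' @param background_reflectance Reflectance of the board/background.
#' @param illum_amplitude Relative amplitude of the smooth illumination
#'   non-uniformity across the sensor line.
#' @param noise_sd Additive sensor noise sd in DN.
#' @param dn_dark,dn_white Nominal dark level and white-frame peak in DN.
#' @param seed Integer seed controlling silhouette and noise.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height = 120, width = 160,
                         wavelengths = default_grid(),
                         plant_fraction = 0.25,
                         background_reflectance = 0.30,
                         illum_amplitude = 0.10, noise_sd = 6,
                         dn_dark = 100, dn_white = 3300, seed = 1) {
  stopifnot(height >= 1, width >= 1, plant_fraction >= 0, plant_fraction < 1,
            noise_sd >= 0, background_reflectance > 0)
  structure(list(height = height, width = width, wavelengths = wavelengths,
                 plant_fraction = plant_fraction,
                 background_reflectance = background_reflectance,
                 illum_amplitude = illum_amplitude, noise_sd = noise_sd,
                 dn_dark = dn_dark, dn_white = dn_white,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Deterministic plant-shaped silhouette: a stem plus grass-like leaf lobes
# radiating from a crown, scaled to approximate the target cover fraction.
plant_silhouette <- function(height, width, fraction, seed = 1) {
  mask <- matrix(FALSE, height, width)
  if (fraction <= 0) return(mask)
  set.seed(seed)
  cy <- height * 0.58
  cx <- width * (0.45 + 0.1 * runif(1))
  n_leaves <- 5L
  angles <- seq(-70, 70, length.out = n_leaves) + rnorm(n_leaves, 0, 6)
  target <- fraction * height * width
  # base leaf half-axes; scaled so total ellipse area ~ target
  base_len <- sqrt(target / n_leaves)
  rows <- matrix(rep(seq_len(height), width), height, width)
  cols <- matrix(rep(seq_len(width), each = height), height, width)
  for (a in angles) {
    th <- (a - 90) * pi / 180  # leaves point upward
    L <- base_len * (1.6 + 0.3 * runif(1))
    W <- base_len * 0.35
    # leaf centre offset along its axis from the crown
    mx <- cx + cos(th) * L * 0.9
    my <- cy + sin(th) * L * 0.9
    u <- (cols - mx) * cos(th) + (rows - my) * sin(th)
    v <- -(cols - mx) * sin(th) + (rows - my) * cos(th)
    mask <- mask | (u^2 / L^2 + v^2 / W^2 <= 1)
  }
  # stem: narrow bar from the crown down
  stem_w <- max(1, round(width * 0.012))
  stem_rows <- seq(floor(cy), min(height, floor(cy + height * 0.3)))
  stem_cols <- seq(max(1, round(cx) - stem_w), min(width, round(cx) + stem_w))
  mask[stem_rows, stem_cols] <- TRUE
  mask
}

#' Render a synthetic line-scan scene
#'
#' Forward model: `raw = dark + gain(band) * illum(col) * reflectance +
#' noise`, where reflectance is the plant endmember inside the silhouette and
#' the flat background level outside. The emitted white frame images the
#' background board through the same optics (per spatial line, so the
#' illumination profile cancels on calibration); the dark frame sits near the
#' bottom of the DN range.
#'
#' @param endmember Plant reflectance spectrum on the scene grid (see
#'   [leaf_endmember()]).
#' @param cfg A [scene_config()].
#' @return List with `raw` (a raw-kind [hyper_cube()]), `refs` (a
#'   [reference_frames()] with `[cols x bands]` dark/white), and `truth_mask`
#'   (logical matrix, the rendered silhouette).
#' @export
render_scene <- function(endmember, cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  wl <- cfg$wavelengths
  if (length(endmember) != length(wl)) {
    stop("endmember length (", length(endmember),
         ") does not match the scene grid (", length(wl), " bands)")
  }
  h <- cfg$height; w <- cfg$width; nb <- length(wl)
  mask <- plant_silhouette(h, w, cfg$plant_fraction, seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  # smooth illumination profile across the sensor line
  phase <- runif(1, 0, 2 * pi)
  cols <- seq_len(w)
  illum <- 1 - cfg$illum_amplitude * ((cols - w / 2) / (w / 2))^2 +
    0.02 * sin(2 * pi * cols / w + phase)
  # halogen-like spectral gain, peaking in the NIR
  gain_b <- 0.45 + 0.55 * exp(-(wl - 900)^2 / (2 * 260^2))
  amp <- (cfg$dn_white - cfg$dn_dark) /
    (max(gain_b) * max(illum) * cfg$background_reflectance)
  dark <- matrix(cfg$dn_dark, w, nb) +
    outer(2 * sin(cols / 13), rep(1, nb))   # mild fixed pattern
  white <- dark + amp * outer(illum, gain_b) * cfg$background_reflectance
  signal <- outer(illum, gain_b) * amp     # [cols x bands]
  raw <- array(0, c(h, w, nb))
  refl_bg <- cfg$background_reflectance
  for (b in seq_len(nb)) {
    refl <- matrix(refl_bg, h, w)
    refl[mask] <- endmember[b]
    dn <- matrix(dark[, b], h, w, byrow = TRUE) +
      refl * matrix(signal[, b], h, w, byrow = TRUE)
    if (cfg$noise_sd > 0) dn <- dn + rnorm(h * w, sd = cfg$noise_sd)
    raw[, , b] <- dn
  }
  list(
    raw = hyper_cube(raw, wl, kind = "raw"),
    refs = reference_frames(dark = dark, white = white),
    truth_mask = mask
  )
}
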