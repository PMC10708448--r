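#' Red-edge convolution window
#'
#' Builds the band window and symmetric integer ramp used by the red-edge
#' segmentation operator. The window spans the bands whose wavelengths fall
#' between the nearest grid bands to `lo` and `hi` (inclusive). If the window
#' has even length it is trimmed by one band from the high-wavelength end so
#' that a symmetric zero-sum ramp `-m..m` exists.
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param lo,hi Window limits in nm; defaults 680 and 732, the characteristic
#'   vegetation red-edge region.
#' @return An object of class `rededge_window` with fields `idx` (band
#'   indices), `lin` (integer ramp) and `wavelengths`.
#' @export
make_window <- function(wavelengths, lo = 680, hi = 732) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 3) stop("wavelength grid too short")
  if (min(wavelengths) > lo || max(wavelengths) < hi) {
    stop(sprintf("grid [%.1f, %.1f] does not cover the window [%g, %g] nm",
                 min(wavelengths), max(wavelengths), lo, hi))
  }
  i_start <- which.min(abs(wavelengths - lo))
  i_end <- which.min(abs(wavelengths - hi))
  idx <- i_start:i_end
  if (length(idx) %% 2 == 0) idx <- idx[-length(idx)]
  if (length(idx) < 3) stop("red-edge window shorter than 3 bands")
  m <- (length(idx) - 1L) / 2L
  structure(list(idx = idx, lin = seq.int(-m, m),
                 wavelengths = wavelengths[idx]),
            class = "rededge_window")
}

#' @export
print.rededge_window <- function(x, ...) {
  cat(sprintf("<rededge_window> %d bands, %.1f-%.1f nm, ramp %d..%d\n",
              length(x$idx), min(x$wavelengths), max(x$wavelengths),
              min(x$lin), max(x$lin)))
  invisible(x)
}

#' Red-edge slope map
#'
#' For every pixel, projects the spectrum over the window bands onto the
#' centred integer ramp: `con[p] = sum_k lin_k x[p,k] / sum_k lin_k^2`, the
#' least-squares slope (per band step) of the spectrum against the ramp.
#' Vegetation's steep red edge gives large positive slopes; flat backgrounds
#' give values near zero.
#'
#' @param cube A reflectance-kind [hyper_cube()].
#' @param win A [make_window()] object built on the cube's grid.
#' @return Numeric matrix `[rows, cols]` of slopes.
#' @export
rededge_slope_map <- function(cube, win) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(win, "rededge_window"))
  if (cube$kind != "reflectance") {
    stop("slope map requires a calibrated (reflectance) cube")
  }
  d <- dim(cube$data)
  if (max(win$idx) > d[3]) stop("window indices exceed cube bands")
  con <- matrix(0, d[1], d[2])
  for (k in seq_along(win$idx)) {
    if (win$lin[k] != 0) {
      con <- con + win$lin[k] * cube$data[, , win$idx[k]]
    }
  }
  con <- con / sum(win$lin^2)
  if (anyNA(con)) warning("NaN/NA in red-edge window bands propagated")
  con
}

#' Red-edge plant segmentation
#'
#' Thresholds the red-edge slope map: `mask = con > threshold` (strict). The
#' default threshold of 7 is calibrated for percent-scale reflectance; with a
#' fraction-scale cube the slope map is multiplied by 100 before
#' thresholding when `reflectance_scale = "percent"` (the default pipeline
#' convention). No morphological post-processing is applied.
#'
#' @param cube A reflectance-kind [hyper_cube()].
#' @param win A [make_window()] object.
#' @param threshold Slope threshold; default 7 (percent reflectance per band
#'   step).
#' @param reflectance_scale `"percent"` (default) rescales fraction-valued
#'   cubes by 100 before thresholding; `"as_is"` thresholds the slope map on
#'   the cube's native scale.
#' @return An object of class `plant_mask`: logical matrix plus the threshold
#'   and window used.
#' @export
segment_plant <- function(cube, win, threshold = 7,
                          reflectance_scale = c("percent", "as_is")) {
  reflectance_scale <- match.arg(reflectance_scale)
  con <- rededge_slope_map(cube, win)
  if (reflectance_scale == "percent") con <- con * 100
  mask <- !is.na(con) & con > threshold
  structure(list(mask = mask, threshold = threshold, window = win,
                 reflectance_scale = reflectance_scale),
            class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> %d x %d, %d plant pixels (threshold %g)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold))
  invisible(x)
}

#' Mean plant spectrum with band cropping
#'
#' Averages the spectrum over all masked plant pixels, then crops to the
#' retained wavelength range (default 460-975 nm, the region with good
#' signal-to-noise). Crop boundaries are inclusive with nearest-band
#' matching.
#'
#' @param cube A reflectance-kind [hyper_cube()].
#' @param mask A [segment_plant()] result or a logical matrix.
#' @param crop Length-2 numeric, nm; `NULL` to skip cropping.
#' @return An object of class `spectrum_record`: `values`, `wavelengths`,
#'   `pixel_count` and the cube's `meta`.
#' @export
mean_spectrum <- function(cube, mask, crop = c(460, 975)) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (inherits(mask, "plant_mask")) mask <- mask$mask
  d <- dim(cube$data)
  if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
    stop("mask must be a logical [rows x cols] matrix matching the cube")
  }
  idx <- which(mask)
  if (length(idx) == 0) stop("no plant pixels: empty segmentation mask")
  bandmat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  values <- colMeans(bandmat[idx, , drop = FALSE])
  wl <- cube$wavelengths
  if (!is.null(crop)) {
    keep <- crop_indices(wl, crop)
    values <- values[keep]
    wl <- wl[keep]
  }
  structure(list(values = values, wavelengths = wl,
                 pixel_count = length(idx), meta = cube$meta),
            class = "spectrum_record")
}

# Inclusive nearest-band crop window.
crop_indices <- function(wavelengths, crop) {
  stopifnot(length(crop) == 2, crop[1] < crop[2])
  i1 <- which.min(abs(wavelengths - crop[1]))
  i2 <- which.min(abs(wavelengths - crop[2]))
  i1:i2
}
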