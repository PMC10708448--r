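#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing; the defaults (polynomial order 1,
#' window 5) make every interior point the 5-point moving average of its
#' neighbourhood and reproduce straight lines exactly. Edges are handled by a
#' one-sided polynomial fit over the first/last window (no padding beyond
#' the measured range).
#'
#' @param x Numeric spectrum.
#' @param window Odd window length.
#' @param order Polynomial order, `< window`.
#' @return Smoothed spectrum, same length.
#' @export
savgol_smooth <- function(x, window = 5, order = 1) {
  stopifnot(window %% 2 == 1, order < window)
  if (length(x) < window) {
    stop("spectrum shorter than the smoothing window (", window, ")")
  }
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Absorbance transform log10(1/R)
#'
#' Elementwise `log10(1/R)` (chemometric absorbance convention). Values at or
#' below `floor` are floored with a warning so the logarithm stays finite.
#'
#' @param x Reflectance vector or matrix.
#' @param floor Positive lower bound; default `1e-4`.
#' @return Transformed values, same shape.
#' @export
log_inverse <- function(x, floor = 1e-4) {
  if (any(x <= floor)) {
    warning("reflectance values <= ", floor, " floored before log(1/R)")
    x <- pmax(x, floor)
  }
  log10(1 / x)
}

#' Multiplicative scatter correction
#'
#' `msc_fit` computes the reference spectrum (the column mean of the training
#' matrix). `msc_apply` regresses each spectrum on the reference,
#' `x = a + b * ref`, by ordinary least squares and returns `(x - a) / b`,
#' removing per-spectrum additive and multiplicative scatter.
#'
#' @param X_train Training matrix `[n x bands]`, `n >= 2`.
#' @param x Spectrum (vector) or matrix of spectra to correct.
#' @param reference Reference spectrum from `msc_fit`.
#' @return `msc_fit`: the reference spectrum. `msc_apply`: corrected
#'   spectrum/matrix.
#' @export
msc_fit <- function(X_train) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 2) stop("MSC needs at least 2 training spectra")
  ref <- colMeans(X_train)
  if (!all(is.finite(ref)) || sd(ref) == 0) {
    stop("MSC reference must be finite and nonconstant")
  }
  ref
}

#' @rdname msc_fit
#' @export
msc_apply <- function(x, reference) {
  one <- function(v) {
    rc <- reference - mean(reference)
    b <- sum(rc * (v - mean(v))) / sum(rc^2)
    if (abs(b) < 1e-12) stop("degenerate spectrum: MSC slope ~ 0")
    a <- mean(v) - b * mean(reference)
    (v - a) / b
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(as.numeric(x))
}

#' Mean centering with train-fit/test-apply semantics
#'
#' @param X_train Training matrix.
#' @param x Vector or matrix to centre.
#' @param means Column means stored by `mean_center_fit`.
#' @return `mean_center_fit`: column means. `mean_center_apply`: centred
#'   data.
#' @export
mean_center_fit <- function(X_train) colMeans(as.matrix(X_train))

#' @rdname mean_center_fit
#' @export
mean_center_apply <- function(x, means) {
  if (is.matrix(x)) sweep(x, 2, means) else as.numeric(x) - means
}

#' Model-side preprocessing chain
#'
#' Fits, on training rows only, the chain applied before both classifiers:
#' `log10(1/R)` then multiplicative scatter correction then mean centering.
#' `preprocess_chain_apply` uses only the fitted parameters, so validation
#' and day-to-day data are transformed without leakage.
#'
#' @param X_train Training reflectance matrix.
#' @param x Reflectance vector or matrix to transform.
#' @param model Fitted chain from `preprocess_chain_fit`.
#' @return `preprocess_chain_fit`: an object of class `preprocess_model`
#'   with `msc_reference`, `col_means` and the chain order descriptor.
#'   `preprocess_chain_apply`: transformed data.
#' @export
preprocess_chain_fit <- function(X_train) {
  A <- suppressWarnings(log_inverse(as.matrix(X_train)))
  ref <- msc_fit(A)
  M <- msc_apply(A, ref)
  mu <- mean_center_fit(M)
  structure(list(msc_reference = ref, col_means = mu,
                 order = c("log10(1/R)", "msc", "mean_center")),
            class = "preprocess_model")
}

#' @rdname preprocess_chain_fit
#' @export
preprocess_chain_apply <- function(model, x) {
  stopifnot(inherits(model, "preprocess_model"))
  A <- suppressWarnings(log_inverse(x))
  M <- msc_apply(A, model$msc_reference)
  mean_center_apply(M, model$col_means)
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat("<preprocess_model> chain:", paste(x$order, collapse = " -> "),
      sprintf("(%d bands)\n", length(x$col_means)))
  invisible(x)
}
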