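#' Default SVM hyperparameter grid
#'
#' Candidates for the exhaustive grid search: a linear kernel over
#' log-spaced C in `[1e-3, 100]` plus an RBF kernel over the same C grid
#' crossed with log-spaced gamma in `[1e-6, 1e-1]` (6 points per axis: 6 + 36
#' candidates). Rows are ordered so that ties resolve to linear kernel, then
#' smaller C, then smaller gamma.
#'
#' @param n_c,n_gamma Points per axis.
#' @param c_range,gamma_range Axis ranges.
#' @param kernels Kernels to include.
#' @return Data frame with columns `kernel`, `cost`, `gamma`.
#' @export
svm_grid <- function(n_c = 6, n_gamma = 6, c_range = c(1e-3, 100),
                     gamma_range = c(1e-6, 1e-1),
                     kernels = c("linear", "radial")) {
  cs <- 10^seq(log10(c_range[1]), log10(c_range[2]), length.out = n_c)
  gs <- 10^seq(log10(gamma_range[1]), log10(gamma_range[2]),
               length.out = n_gamma)
  out <- NULL
  if ("linear" %in% kernels) {
    out <- rbind(out, data.frame(kernel = "linear", cost = cs, gamma = NA))
  }
  if ("radial" %in% kernels) {
    out <- rbind(out, expand.grid(kernel = "radial", gamma = gs, cost = cs,
                                  stringsAsFactors = FALSE)[, c("kernel", "cost", "gamma")])
  }
  out[order(match(out$kernel, c("linear", "radial")), out$cost, out$gamma), ,
      drop = FALSE]
}

# Fit one binary SVM with Platt-style sigmoid probability calibration.
# y is 0/1; decision values are oriented so larger values mean class 1.
svm_fit_binary <- function(X, y, kernel, cost, gamma = NULL) {
  yf <- factor(y, levels = c(0, 1))
  if (nlevels(droplevels(yf)) < 2) stop("single-class training labels")
  args <- list(x = X, y = yf, type = "C-classification", kernel = kernel,
               cost = cost, scale = FALSE)
  if (identical(kernel, "radial")) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  d <- as.numeric(attr(predict(fit, X, decision.values = TRUE),
                       "decision.values"))
  sgn <- if (mean(d[y == 1]) >= mean(d[y == 0])) 1 else -1
  d <- sgn * d
  # Platt calibration with regularized targets, so separable training sets
  # still yield a finite sigmoid
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  t_soft <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  cal <- tryCatch(
    suppressWarnings(coef(glm(t_soft ~ d, family = binomial()))),
    error = function(e) c(0, 0))
  if (!all(is.finite(cal)) || cal[2] < 0) {
    cal <- c(stats::qlogis(mean(t_soft)), 0)  # monotone (constant) fallback
  }
  structure(list(fit = fit, sign = sgn, platt = unname(cal),
                 kernel = kernel, cost = cost, gamma = gamma),
            class = "binary_svm")
}

# P(class 1 | x) from the calibrated decision value.
svm_prob <- function(model, newdata) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  d <- model$sign * as.numeric(attr(
    predict(model$fit, newdata, decision.values = TRUE), "decision.values"))
  plogis(model$platt[1] + model$platt[2] * d)
}

#' @export
print.binary_svm <- function(x, ...) {
  cat(sprintf("<binary_svm> kernel=%s, C=%g%s\n", x$kernel, x$cost,
              if (is.null(x$gamma) || is.na(x$gamma)) ""
              else sprintf(", gamma=%g", x$gamma)))
  invisible(x)
}

# LOO RMSE between calibrated probabilities and the 0/1 labels.
svm_loo_rmse <- function(X, y, kernel, cost, gamma) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) return(Inf)
    m <- svm_fit_binary(X[-i, , drop = FALSE], yi, kernel, cost, gamma)
    pred[i] <- svm_prob(m, X[i, , drop = FALSE])
  }
  sqrt(mean((pred - y)^2))
}

#' Select a binary SVM by grid search on cross-validated RMSE
#'
#' Scores every grid candidate by leave-one-out RMSE between the calibrated
#' class probability and the {0,1} labels and refits the global minimiser on
#' the full data. Ties resolve in grid order: linear kernel first, then
#' smaller C, then smaller gamma. A single-candidate grid skips the
#' cross-validation entirely.
#'
#' @param X Training matrix (already preprocessed).
#' @param y 0/1 response.
#' @param grid Candidate table from [svm_grid()] (or any subset of it).
#' @return The selected `binary_svm`, with attribute `rmsecv` over the grid.
#' @export
select_svm <- function(X, y, grid = svm_grid()) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("single-class training labels")
  if (nrow(grid) == 1) {
    model <- svm_fit_binary(X, y, grid$kernel[1], grid$cost[1], grid$gamma[1])
    attr(model, "rmsecv") <- NA_real_
    return(model)
  }
  rms <- vapply(seq_len(nrow(grid)), function(k) {
    svm_loo_rmse(X, y, grid$kernel[k], grid$cost[k], grid$gamma[k])
  }, numeric(1))
  k <- which.min(rms)  # first minimum = tie-break order of the grid
  model <- svm_fit_binary(X, y, grid$kernel[k], grid$cost[k], grid$gamma[k])
  attr(model, "rmsecv") <- rms
  model
}
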