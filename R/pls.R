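#' Partial least squares regression (PLS1, NIPALS)
#'
#' Fits a univariate PLS regression of a {0,1}-coded response on the spectra
#' with the requested number of latent variables; the discriminant use
#' ("PLS-DA") treats the continuous prediction as a class score. X and y are
#' centred internally (the preprocessing chain has already mean-centred the
#' training matrix, so these means are ~0, but storing them keeps prediction
#' self-contained).
#'
#' @param X Numeric matrix `[n x p]`.
#' @param y Numeric response, coded 0/1 for discrimination.
#' @param n_lv Number of latent variables (>= 1; at most the rank of the
#'   centred X).
#' @return An object of class `binary_plsda` with weights `W`, loadings `P`,
#'   regression coefficients and centring terms.
#' @export
pls_fit <- function(X, y, n_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), n_lv >= 1)
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2, xbar); f <- y - ybar
  r <- qr(E)$rank
  if (n_lv > r) {
    stop("n_lv (", n_lv, ") exceeds the rank of the centred training matrix (",
         r, ")")
  }
  p <- ncol(X)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); qv <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop("degenerate component ", a, ": residual covariance ~ 0")
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(E, t_)[, 1] / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %*% t(p_)
    f <- f - q_ * t_
    W[, a] <- w; P[, a] <- p_; qv[a] <- q_
  }
  B <- W %*% solve(crossprod(P, W), qv)
  structure(list(W = W, P = P, q = qv, coef = B[, 1], xbar = xbar,
                 ybar = ybar, n_lv = n_lv),
            class = "binary_plsda")
}

#' @rdname pls_fit
#' @param model A fitted `binary_plsda`.
#' @param newdata Matrix or vector of new spectra.
#' @return `pls_predict`: continuous prediction(s) of the coded response.
#' @export
pls_predict <- function(model, newdata) {
  stopifnot(inherits(model, "binary_plsda"))
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  as.numeric(sweep(newdata, 2, model$xbar) %*% model$coef + model$ybar)
}

#' @export
print.binary_plsda <- function(x, ...) {
  cat(sprintf("<binary_plsda> %d latent variable(s), %d bands\n",
              x$n_lv, length(x$coef)))
  invisible(x)
}

# LOO RMSE between continuous PLS predictions and the 0/1 labels.
pls_loo_rmse <- function(X, y, n_lv) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- pls_fit(X[-i, , drop = FALSE], y[-i], n_lv)
    pred[i] <- pls_predict(m, X[i, , drop = FALSE])
  }
  sqrt(mean((pred - y)^2))
}

#' Select a PLS-DA model by cross-validated RMSE
#'
#' Evaluates candidate latent-variable counts by leave-one-out RMSE between
#' the continuous prediction and the {0,1} labels (RMSEcv) and refits the
#' minimiser on the full data. Ties go to the smaller model.
#'
#' @param X Training matrix (already preprocessed).
#' @param y 0/1 response.
#' @param lv_grid Candidate LV counts; default `1:3`. Candidates exceeding
#'   the training rank are dropped.
#' @return The selected `binary_plsda`, with attributes `rmsecv` (named
#'   vector over candidates) and `lv_grid`.
#' @export
select_plsda <- function(X, y, lv_grid = 1:3) {
  X <- as.matrix(X); y <- as.numeric(y)
  r <- qr(sweep(X, 2, colMeans(X)))$rank
  # inside LOO one row is dropped, so keep candidates feasible in every fold
  lv_grid <- lv_grid[lv_grid <= max(1, r - 1)]
  if (length(lv_grid) == 0) lv_grid <- 1
  if (length(lv_grid) == 1) {
    best <- lv_grid
    rms <- NA_real_
  } else {
    rms <- vapply(lv_grid, function(a) pls_loo_rmse(X, y, a), numeric(1))
    best <- lv_grid[which.min(rms)]  # which.min takes the first = fewest LVs
  }
  model <- pls_fit(X, y, best)
  attr(model, "rmsecv") <- stats::setNames(rms, lv_grid)
  attr(model, "lv_grid") <- lv_grid
  model
}
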