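#' Normalized difference vegetation index
#'
#' `(R_nir - R_red) / (R_nir + R_red)` with nearest-band lookup of the red
#' and NIR wavelengths inside the cropped grid.
#'
#' @param values Reflectance spectrum, or a [spectra_table()] (one NDVI per
#'   row).
#' @param wavelengths Grid matching `values` (ignored for tables).
#' @param red_nm,nir_nm Band positions, nm; defaults 670 and 800.
#' @return NDVI value(s).
#' @export
ndvi <- function(values, wavelengths = NULL, red_nm = 670, nir_nm = 800) {
  if (inherits(values, "spectrum_record")) {
    wavelengths <- values$wavelengths
    values <- values$values
  }
  if (inherits(values, "spectra_table")) {
    tab <- values
    i_red <- which.min(abs(tab$wavelengths - red_nm))
    i_nir <- which.min(abs(tab$wavelengths - nir_nm))
    den <- tab$X[, i_nir] + tab$X[, i_red]
    if (any(den == 0)) stop("R_nir + R_red is zero for some sample")
    return((tab$X[, i_nir] - tab$X[, i_red]) / den)
  }
  stopifnot(length(values) == length(wavelengths))
  i_red <- which.min(abs(wavelengths - red_nm))
  i_nir <- which.min(abs(wavelengths - nir_nm))
  den <- values[i_nir] + values[i_red]
  if (den == 0) stop("R_nir + R_red is zero")
  (values[i_nir] - values[i_red]) / den
}

#' Pairwise Welch t-tests across classes
#'
#' Two-sided two-sample t-tests with unequal variances (Welch) on a scalar
#' response (typically NDVI) for every unordered pair of classes. Classes
#' are independent plant groups, so an unpaired test is used.
#'
#' @param values Numeric response vector.
#' @param classes Class label per value.
#' @param class_order Optional ordering of classes for the matrix.
#' @return An object of class `pvalue_matrix`: symmetric K x K matrix of
#'   p-values with `NA` diagonal; classes with fewer than 2 values yield
#'   `NA` rows/columns with a warning.
#' @export
pairwise_ttest <- function(values, classes, class_order = NULL) {
  stopifnot(length(values) == length(classes))
  if (is.null(class_order)) {
    canon <- canonical_classes()
    present <- unique(classes)
    class_order <- c(intersect(canon, present), setdiff(present, canon))
  }
  K <- length(class_order)
  P <- matrix(NA_real_, K, K, dimnames = list(class_order, class_order))
  groups <- split(values, factor(classes, levels = class_order))
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small) > 0) {
    warning("classes with < 2 samples left undefined: ",
            paste(small, collapse = ", "))
  }
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      a <- groups[[class_order[i]]]
      b <- groups[[class_order[j]]]
      if (length(a) < 2 || length(b) < 2) next
      p <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
        1  # identical constant groups: no evidence of difference
      } else {
        t.test(a, b, var.equal = FALSE)$p.value
      }
      P[i, j] <- P[j, i] <- p
    }
  }
  structure(list(p = P, classes = class_order,
                 test = "Welch two-sample t, two-sided"),
            class = "pvalue_matrix")
}

#' @export
print.pvalue_matrix <- function(x, ...) {
  cat("<pvalue_matrix>", x$test, "\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Random-forest band importance
#'
#' Fits a 100-tree random forest on a binary contrast of the spectra table
#' and reports the normalized impurity-based (mean decrease in Gini) band
#' importances and the top band. The contrast is either one class against
#' all others (`one_vs_all`) or one class pair restricted to its own rows
#' (`pair`).
#'
#' @param table A [spectra_table()].
#' @param comparison For `mode = "one_vs_all"` a single class name; for
#'   `mode = "pair"` a length-2 character vector.
#' @param mode Comparison mode.
#' @param n_estimators Number of trees (default 100).
#' @param seed RNG seed for the forest (default 42).
#' @return An object of class `band_importance`: normalized `importance`
#'   vector, `top_band_nm`, the comparison and forest settings.
#' @export
band_importance <- function(table, comparison,
                            mode = c("one_vs_all", "pair"),
                            n_estimators = 100, seed = 42) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "spectra_table"))
  lab <- table$meta$treatment
  if (mode == "one_vs_all") {
    stopifnot(length(comparison) == 1)
    if (!comparison %in% lab) stop("class not present: ", comparison)
    y <- factor(ifelse(lab == comparison, comparison, "rest"),
                levels = c("rest", comparison))
    X <- table$X
  } else {
    stopifnot(length(comparison) == 2)
    keep <- lab %in% comparison
    X <- table$X[keep, , drop = FALSE]
    y <- factor(lab[keep], levels = comparison)
  }
  if (nlevels(droplevels(y)) < 2) {
    stop("band importance needs two non-empty classes")
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_estimators,
                                   importance = FALSE)
  imp <- rf$importance[, "MeanDecreaseGini"]
  if (sum(imp) <= 0) imp <- rep(1, length(imp))  # featureless forest
  imp <- imp / sum(imp)
  structure(list(importance = as.numeric(imp),
                 wavelengths = table$wavelengths,
                 top_band_nm = table$wavelengths[which.max(imp)],
                 comparison = comparison, mode = mode,
                 n_estimators = n_estimators, seed = seed),
            class = "band_importance")
}

#' Top-band heatmap over all class pairs
#'
#' Runs pairwise [band_importance()] for every unordered class pair present
#' and assembles the symmetric K x K matrix of top-band wavelengths
#' (diagonal undefined).
#'
#' @param table A [spectra_table()].
#' @param class_order Optional class ordering.
#' @param ... Passed to [band_importance()].
#' @return Symmetric numeric matrix of top-band nm with `NA` diagonal.
#' @export
importance_heatmap <- function(table, class_order = NULL, ...) {
  stopifnot(inherits(table, "spectra_table"))
  present <- unique(table$meta$treatment)
  if (is.null(class_order)) {
    class_order <- c(intersect(canonical_classes(), present),
                     setdiff(present, canonical_classes()))
  }
  K <- length(class_order)
  M <- matrix(NA_real_, K, K, dimnames = list(class_order, class_order))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      bi <- band_importance(table, c(class_order[i], class_order[j]),
                            mode = "pair", ...)
      M[i, j] <- M[j, i] <- bi$top_band_nm
    }
  }
  M
}

#' Render an annotated matrix heatmap to PNG
#'
#' Minimal base-graphics heatmap used for the p-value and top-band matrices.
#'
#' @param M Numeric matrix with dimnames.
#' @param path Output PNG path.
#' @param main Plot title.
#' @param digits Digits for cell annotations.
#' @return `path`, invisibly.
#' @export
plot_matrix_heatmap <- function(M, path, main = "", digits = 2) {
  K <- nrow(M)
  png(path, width = 180 + 60 * K, height = 160 + 60 * K)
  on.exit(dev.off(), add = TRUE)
  par(mar = c(7, 7, 3, 1))  # device-local; dies with dev.off()
  z <- t(M[K:1, , drop = FALSE])
  image(seq_len(K), seq_len(K), z, col = hcl.colors(64, "Blue-Red"),
        axes = FALSE, xlab = "", ylab = "", main = main)
  axis(1, at = seq_len(K), labels = colnames(M), las = 2)
  axis(2, at = seq_len(K), labels = rev(rownames(M)), las = 2)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      v <- M[K + 1 - j, i]
      if (!is.na(v)) text(i, j, format(round(v, digits), nsmall = 0))
    }
  }
  invisible(path)
}
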