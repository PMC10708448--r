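#' Learner family descriptor
#'
#' Describes the binary learner the one-vs-one ensemble uses for every class
#' pair. With `lv` / `grid` left `NULL` the full RMSEcv selection runs per
#' binary problem (LV count 1-3 for PLS-DA, the [svm_grid()] search for the
#' SVM); supplying a fixed `lv` or a single-row `grid` fixes the
#' hyperparameters and skips the inner cross-validation.
#'
#' @param family `"plsda"` or `"svm"`.
#' @param lv PLS-DA: fixed LV count, or `NULL` to select over `lv_grid`.
#' @param lv_grid PLS-DA candidate LV counts.
#' @param grid SVM: candidate grid (defaults to the full [svm_grid()]).
#' @return An object of class `soa_learner`.
#' @export
make_learner <- function(family = c("plsda", "svm"), lv = NULL,
                         lv_grid = 1:3, grid = NULL) {
  family <- match.arg(family)
  if (family == "svm" && is.null(grid)) grid <- svm_grid()
  structure(list(family = family, lv = lv, lv_grid = lv_grid, grid = grid),
            class = "soa_learner")
}

fit_binary_learner <- function(learner, X, y) {
  if (learner$family == "plsda") {
    if (!is.null(learner$lv)) pls_fit(X, y, learner$lv)
    else select_plsda(X, y, lv_grid = learner$lv_grid)
  } else {
    select_svm(X, y, grid = learner$grid)
  }
}

#' Binary class-1 probability
#'
#' For a PLS-DA model the continuous prediction of the {0,1} response is
#' clipped to `[0, 1]` and read as P(class 1); for an SVM the Platt-calibrated
#' sigmoid of the decision value is returned.
#'
#' @param model A `binary_plsda` or `binary_svm`.
#' @param newdata Spectrum vector or matrix (in the model's preprocessed
#'   space).
#' @return Probability vector in `[0, 1]`.
#' @export
binary_probability <- function(model, newdata) {
  if (inherits(model, "binary_plsda")) {
    pmin(pmax(pls_predict(model, newdata), 0), 1)
  } else if (inherits(model, "binary_svm")) {
    svm_prob(model, newdata)
  } else {
    stop("unsupported binary model class")
  }
}

#' Soft voting over one-vs-one pair probabilities
#'
#' For each class, averages its probability over the K-1 binary models that
#' involve it; the predicted class is the argmax, ties resolving to the
#' earliest class in canonical order.
#'
#' @param pair_probs Data frame with columns `class_a`, `class_b`, `p_a`
#'   (probability of `class_a` in that pair's binary model), one row per
#'   unordered pair.
#' @param classes Class order used for tie-breaking.
#' @return List with `class` (predicted label) and `avg_prob` (named
#'   per-class average probabilities).
#' @export
soft_vote <- function(pair_probs, classes) {
  stopifnot(all(c("class_a", "class_b", "p_a") %in% names(pair_probs)))
  avg <- vapply(classes, function(cl) {
    pa <- pair_probs$p_a[pair_probs$class_a == cl]
    pb <- 1 - pair_probs$p_a[pair_probs$class_b == cl]
    mean(c(pa, pb))
  }, numeric(1))
  list(class = classes[which.max(avg)], avg_prob = avg)
}

#' Train a one-vs-one soft-voting ensemble
#'
#' Decomposes the K-class problem into K(K-1)/2 binary problems. For each
#' unordered class pair the preprocessing chain and the selected learner are
#' fitted on that pair's rows only; a preprocessing chain fitted on the full
#' training set is stored for prediction (one reference spectrum serves all
#' pairs when the incoming sample's pair is unknown).
#'
#' @param table A [spectra_table()] of training rows.
#' @param learner A [make_learner()] descriptor.
#' @param classes Class order; defaults to the canonical order restricted to
#'   the classes present. Labels present in `classes` but absent from the
#'   data are dropped.
#' @return An object of class `ovo_ensemble`.
#' @export
ovo_train <- function(table, learner = make_learner("svm"), classes = NULL) {
  stopifnot(inherits(table, "spectra_table"), inherits(learner, "soa_learner"))
  lab <- table$meta$treatment
  if (is.null(classes)) {
    classes <- c(intersect(canonical_classes(), unique(lab)),
                 setdiff(unique(lab), canonical_classes()))
  } else {
    classes <- intersect(classes, unique(lab))
  }
  if (length(classes) < 2) stop("need at least 2 classes")
  counts <- table(factor(lab, levels = classes))
  if (any(counts < 2)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  full_chain <- preprocess_chain_fit(table$X[lab %in% classes, , drop = FALSE])
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    keep <- lab %in% pr
    Xp <- table$X[keep, , drop = FALSE]
    chain <- preprocess_chain_fit(Xp)
    Z <- preprocess_chain_apply(chain, Xp)
    y <- as.numeric(lab[keep] == pr[1])  # class_a coded 1
    fit <- fit_binary_learner(learner, Z, y)
    list(class_a = pr[1], class_b = pr[2], chain = chain, fit = fit)
  })
  structure(list(classes = classes, models = models, full_chain = full_chain,
                 learner = learner, wavelengths = table$wavelengths),
            class = "ovo_ensemble")
}

#' @export
print.ovo_ensemble <- function(x, ...) {
  cat(sprintf("<ovo_ensemble> %d classes, %d binary %s models\n",
              length(x$classes), length(x$models), x$learner$family))
  invisible(x)
}

#' Predict with a one-vs-one ensemble
#'
#' Each incoming spectrum is preprocessed with the stored full-training
#' chain (default) or with each pair's own chain, pushed through every
#' binary model, and soft-voted.
#'
#' @param object An [ovo_train()] ensemble.
#' @param newdata A [spectra_table()] or numeric matrix of raw (reflectance)
#'   spectra.
#' @param transform `"full"` applies the full-training preprocessing chain to
#'   the sample for all binary models; `"per_pair"` applies each pair's own
#'   chain.
#' @param ... Unused.
#' @return List with `class` (predicted labels), `prob` (n x K matrix of
#'   per-class average probabilities) and `pair_probs` (per-pair
#'   probabilities, n x K(K-1)/2).
#' @export
predict.ovo_ensemble <- function(object, newdata,
                                 transform = c("full", "per_pair"), ...) {
  transform <- match.arg(transform)
  X <- if (inherits(newdata, "spectra_table")) newdata$X else as.matrix(newdata)
  n <- nrow(X)
  K <- length(object$classes)
  Zfull <- if (transform == "full") {
    preprocess_chain_apply(object$full_chain, X)
  } else NULL
  npairs <- length(object$models)
  PP <- matrix(NA_real_, n, npairs)
  for (m in seq_len(npairs)) {
    mod <- object$models[[m]]
    Z <- if (transform == "full") Zfull
         else preprocess_chain_apply(mod$chain, X)
    PP[, m] <- binary_probability(mod$fit, Z)
  }
  class_a <- vapply(object$models, `[[`, character(1), "class_a")
  class_b <- vapply(object$models, `[[`, character(1), "class_b")
  prob <- matrix(NA_real_, n, K, dimnames = list(NULL, object$classes))
  labels <- character(n)
  for (i in seq_len(n)) {
    sv <- soft_vote(data.frame(class_a = class_a, class_b = class_b,
                               p_a = PP[i, ]), object$classes)
    prob[i, ] <- sv$avg_prob
    labels[i] <- sv$class
  }
  colnames(PP) <- paste(class_a, class_b, sep = "|")
  list(class = labels, prob = prob, pair_probs = PP)
}
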