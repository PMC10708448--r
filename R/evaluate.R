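#' Confusion report
#'
#' K x K confusion counts (rows = true, cols = predicted) with per-class
#' accuracy/error, overall accuracy (correct / total) and error rate
#' (1 - OA).
#'
#' @param true,predicted Label vectors of equal length.
#' @param classes Class order; every label must belong to it.
#' @param descriptor Optional named list describing the experiment (train
#'   days/rounds, CV scheme, ...), carried on the report.
#' @return An object of class `confusion_report`.
#' @export
confusion <- function(true, predicted, classes = NULL,
                      descriptor = list()) {
  stopifnot(length(true) == length(predicted))
  if (is.null(classes)) {
    present <- unique(c(true, predicted))
    classes <- c(intersect(canonical_classes(), present),
                 setdiff(present, canonical_classes()))
  }
  unknown <- setdiff(unique(c(true, predicted)), classes)
  if (length(unknown) > 0) {
    stop("labels outside the class order: ", paste(unknown, collapse = ", "))
  }
  counts <- table(factor(true, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(true = classes, predicted = classes))
  rs <- rowSums(counts)
  acc <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  oa <- sum(diag(counts)) / sum(counts)
  structure(list(counts = counts, classes = classes,
                 per_class_accuracy = acc, per_class_error = 1 - acc,
                 overall_accuracy = oa, error_rate = 1 - oa,
                 n = sum(counts), descriptor = descriptor),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("<confusion_report> OA = %.3f (error %.3f), n = %d\n",
              x$overall_accuracy, x$error_rate, x$n))
  print(x$counts)
  invisible(x)
}

#' Leave-one-out cross-validated OVO experiment
#'
#' For every retained row, trains the full one-vs-one ensemble (preprocessing
#' refit per fold, no leakage) on all other rows and predicts the held-out
#' row; predictions are aggregated into a confusion report. Binary models
#' for class pairs that do not involve the held-out sample's class are
#' mathematically identical to the full-data pair models (their training
#' rows are unchanged by the fold) and are computed once.
#'
#' @param table A [spectra_table()].
#' @param dat,rounds Optional filters applied before cross-validation.
#' @param learner A [make_learner()] descriptor.
#' @param transform Prediction-time preprocessing mode, see
#'   [predict.ovo_ensemble()].
#' @param exclude_flagged Drop flagged outlier samples (all their rows)
#'   before the experiment.
#' @return A `confusion_report` tagged with the experiment descriptor.
#' @export
loo_experiment <- function(table, dat = NULL, rounds = NULL,
                           learner = make_learner("svm"),
                           transform = c("full", "per_pair"),
                           exclude_flagged = TRUE) {
  transform <- match.arg(transform)
  tab <- st_filter(table, dat = dat, rounds = rounds)
  if (exclude_flagged) tab <- exclude_outliers(tab, quiet = TRUE)
  lab <- tab$meta$treatment
  classes <- c(intersect(canonical_classes(), unique(lab)),
               setdiff(unique(lab), canonical_classes()))
  n <- nrow(tab$X)
  # cache: pair models not involving class(i) equal the full-data pair models
  full_fit <- ovo_train(tab, learner, classes = classes)
  pair_a <- vapply(full_fit$models, `[[`, character(1), "class_a")
  pair_b <- vapply(full_fit$models, `[[`, character(1), "class_b")
  truth <- character(0); pred <- character(0); skipped <- 0L
  for (i in seq_len(n)) {
    cls_i <- lab[i]
    train_lab <- lab[-i]
    if (sum(train_lab == cls_i) < 2 ||
        length(unique(train_lab)) < 2) {
      skipped <- skipped + 1L
      warning("skipping sample ", tab$meta$sample_id[i],
              ": a class has fewer than 2 training samples in its fold")
      next
    }
    fold <- full_fit
    fold$full_chain <- preprocess_chain_fit(tab$X[-i, , drop = FALSE])
    refit <- which(pair_a == cls_i | pair_b == cls_i)
    for (m in refit) {
      pr <- c(pair_a[m], pair_b[m])
      keep <- which(lab %in% pr & seq_len(n) != i)
      Xp <- tab$X[keep, , drop = FALSE]
      chain <- preprocess_chain_fit(Xp)
      Z <- preprocess_chain_apply(chain, Xp)
      y <- as.numeric(lab[keep] == pr[1])
      fold$models[[m]] <- list(class_a = pr[1], class_b = pr[2],
                               chain = chain,
                               fit = fit_binary_learner(learner, Z, y))
    }
    p <- predict(fold, tab$X[i, , drop = FALSE], transform = transform)
    truth <- c(truth, cls_i)
    pred <- c(pred, p$class)
  }
  confusion(truth, pred, classes,
            descriptor = list(cv = "leave-one-out", dat = dat,
                              rounds = rounds, learner = learner$family,
                              transform = transform,
                              preprocess = "refit per fold",
                              skipped = skipped))
}

#' Day-to-day validation
#'
#' Trains one ensemble on all rows of the training day(s) and predicts all
#' rows of the test day(s); no fitted parameter touches the test data.
#' Identical (sample id, DAT) rows appearing in both sets are a protocol
#' violation and raise an error unless `allow_overlap = TRUE` (useful only
#' for resubstitution diagnostics).
#'
#' @param table A [spectra_table()].
#' @param train_dat,test_dat DAT value(s) for training and testing.
#' @param learner A [make_learner()] descriptor.
#' @param rounds Optional round filter applied to both sets.
#' @param transform Prediction-time preprocessing mode.
#' @param exclude_flagged Drop flagged outlier samples first.
#' @param allow_overlap Permit train/test overlap (resubstitution).
#' @return A `confusion_report`.
#' @export
day_to_day <- function(table, train_dat, test_dat,
                       learner = make_learner("svm"), rounds = NULL,
                       transform = c("full", "per_pair"),
                       exclude_flagged = TRUE, allow_overlap = FALSE) {
  transform <- match.arg(transform)
  tab <- table
  if (exclude_flagged) tab <- exclude_outliers(tab, quiet = TRUE)
  train <- st_filter(tab, dat = train_dat, rounds = rounds)
  test <- st_filter(tab, dat = test_dat, rounds = rounds)
  if (nrow(train$X) == 0 || nrow(test$X) == 0) {
    stop("train or test day has no rows")
  }
  key <- function(m) paste(m$sample_id, m$dat)
  overlap <- intersect(key(train$meta), key(test$meta))
  if (length(overlap) > 0 && !allow_overlap) {
    stop("protocol violation: ", length(overlap),
         " identical (sample id, DAT) rows in both train and test")
  }
  test_classes <- unique(test$meta$treatment)
  train_classes <- unique(train$meta$treatment)
  if (length(intersect(test_classes, train_classes)) == 0) {
    stop("disjoint class sets between train and test days")
  }
  missing <- setdiff(test_classes, train_classes)
  if (length(missing) > 0) {
    stop("test-day class(es) absent from training day: ",
         paste(missing, collapse = ", "))
  }
  fit <- ovo_train(train, learner)
  p <- predict(fit, test, transform = transform)
  confusion(test$meta$treatment, p$class, fit$classes,
            descriptor = list(cv = "day-to-day", train_dat = train_dat,
                              test_dat = test_dat, rounds = rounds,
                              learner = learner$family,
                              transform = transform))
}

#' Remove outlier samples
#'
#' Removes every row (all days, all rounds) of the given sample ids; by
#' default the ids are taken from the table's outlier flags. Flagging an
#' absent id warns and is otherwise a no-op.
#'
#' @param table A [spectra_table()].
#' @param sample_ids Ids to drop; `NULL` uses the rows flagged
#'   `outlier = TRUE`.
#' @param quiet Suppress the removal message.
#' @return The filtered [spectra_table()].
#' @export
exclude_outliers <- function(table, sample_ids = NULL, quiet = FALSE) {
  stopifnot(inherits(table, "spectra_table"))
  if (is.null(sample_ids)) {
    sample_ids <- unique(table$meta$sample_id[table$meta$outlier])
  }
  if (length(sample_ids) == 0) return(table)
  absent <- setdiff(sample_ids, table$meta$sample_id)
  if (length(absent) > 0) {
    warning("sample id(s) not present, ignored: ",
            paste(absent, collapse = ", "))
  }
  if (length(setdiff(sample_ids, absent)) == 0) return(table)
  keep <- !(table$meta$sample_id %in% sample_ids)
  if (!quiet) {
    message("excluding ", sum(!keep), " rows from ",
            length(setdiff(sample_ids, absent)), " outlier sample(s)")
  }
  spectra_table(table$X[keep, , drop = FALSE], table$wavelengths,
                table$meta[keep, , drop = FALSE])
}

#' Render a confusion report to CSV and PNG
#'
#' Writes `<prefix>.csv` (counts with per-class accuracy and error columns)
#' and `<prefix>.png` (annotated heatmap with the OA in the title). The CSV
#' round-trips through [read_confusion_csv()].
#'
#' @param report A `confusion_report`.
#' @param prefix Output path prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
render_report <- function(report, prefix) {
  stopifnot(inherits(report, "confusion_report"))
  df <- as.data.frame.matrix(report$counts)
  df$accuracy <- report$per_class_accuracy
  df$error <- report$per_class_error
  csv <- paste0(prefix, ".csv")
  write.csv(cbind(true = rownames(df), df), csv, row.names = FALSE)
  pngf <- paste0(prefix, ".png")
  K <- length(report$classes)
  png(pngf, width = 220 + 60 * K, height = 200 + 60 * K)
  op <- par(mar = c(7, 7, 4, 1))
  z <- t(report$counts[K:1, , drop = FALSE])
  image(seq_len(K), seq_len(K), z, col = hcl.colors(64, "Blues 3", rev = TRUE),
        axes = FALSE, xlab = "", ylab = "",
        main = sprintf("OA = %.1f%% (n = %d)",
                       100 * report$overall_accuracy, report$n))
  axis(1, at = seq_len(K), labels = report$classes, las = 2)
  axis(2, at = seq_len(K), labels = rev(report$classes), las = 2)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    text(i, j, report$counts[K + 1 - j, i])
  }
  par(op)
  dev.off()
  invisible(c(csv = csv, png = pngf))
}

#' @rdname render_report
#' @param path CSV path written by [render_report()].
#' @return `read_confusion_csv`: the reconstructed `confusion_report`.
#' @export
read_confusion_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  classes <- df$true
  counts <- as.matrix(df[, classes, drop = FALSE])
  rownames(counts) <- classes
  # reconstruct from expanded label pairs so all derived rates are recomputed
  long_true <- character(0); long_pred <- character(0)
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    k <- counts[i, j]
    if (k > 0) {
      long_true <- c(long_true, rep(classes[i], k))
      long_pred <- c(long_pred, rep(classes[j], k))
    }
  }
  confusion(long_true, long_pred, classes)
}
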