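#' Spectra table
#'
#' The modelling dataset: a samples-by-bands reflectance matrix with per-row
#' labels (treatment, SOA target, MOA group, days after treatment, round,
#' sample id, outlier flag).
#'
#' @param X Numeric matrix `[n x bands]`.
#' @param wavelengths Numeric vector, one per column, nm.
#' @param meta Data frame with columns `sample_id`, `treatment`, `soa`,
#'   `moa_group`, `dat`, `round`, `outlier` and one row per row of `X`.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(X, wavelengths, meta) {
  X <- as.matrix(X)
  meta <- as.data.frame(meta)
  if (ncol(X) != length(wavelengths)) {
    stop("column count (", ncol(X), ") does not match wavelength count (",
         length(wavelengths), ")")
  }
  if (nrow(X) != nrow(meta)) stop("X and meta row counts differ")
  needed <- c("sample_id", "treatment", "soa", "moa_group", "dat", "round",
              "outlier")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    stop("meta lacks columns: ", paste(missing, collapse = ", "))
  }
  key <- paste(meta$sample_id, meta$dat, meta$round)
  if (anyDuplicated(key)) {
    stop("duplicated (sample_id, dat, round) combination in meta")
  }
  structure(list(X = X, wavelengths = as.numeric(wavelengths), meta = meta),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf(
    "<spectra_table> %d spectra x %d bands (%.1f-%.1f nm); %d classes, DAT %s\n",
    nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths),
    length(unique(x$meta$treatment)),
    paste(sort(unique(x$meta$dat)), collapse = ",")))
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$X)

#' Subset a spectra table by row index or metadata filters
#'
#' @param table A [spectra_table()].
#' @param rows Integer or logical row index (applied first if given).
#' @param dat,rounds,treatments Optional filters on the metadata columns;
#'   vectors select multiple values (e.g. `rounds = c(1, 2)` for
#'   combined-round training).
#' @return A filtered [spectra_table()].
#' @export
st_filter <- function(table, rows = NULL, dat = NULL, rounds = NULL,
                      treatments = NULL) {
  stopifnot(inherits(table, "spectra_table"))
  keep <- rep(TRUE, nrow(table$X))
  if (!is.null(rows)) {
    sel <- rep(FALSE, nrow(table$X))
    sel[rows] <- TRUE
    keep <- keep & sel
  }
  if (!is.null(dat)) keep <- keep & table$meta$dat %in% dat
  if (!is.null(rounds)) keep <- keep & table$meta$round %in% rounds
  if (!is.null(treatments)) keep <- keep & table$meta$treatment %in% treatments
  spectra_table(table$X[keep, , drop = FALSE], table$wavelengths,
                table$meta[keep, , drop = FALSE])
}

#' Read/write the spectra interchange CSV
#'
#' Columns: `sample_id, treatment, soa, moa_group, dat, round, outlier`, then
#' one reflectance column per wavelength named `wl_<nm>`.
#'
#' @param table A [spectra_table()].
#' @param path CSV path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a [spectra_table()].
#' @export
write_spectra_csv <- function(table, path) {
  stopifnot(inherits(table, "spectra_table"))
  wl_names <- paste0("wl_", formatC(table$wavelengths, format = "f",
                                    digits = 4))
  df <- cbind(table$meta, as.data.frame(table$X) |>
                stats::setNames(wl_names))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df))
  if (length(wl_cols) == 0) stop("no wavelength columns (wl_*) in ", path)
  wavelengths <- as.numeric(sub("^wl_", "", names(df)[wl_cols]))
  meta <- df[, -wl_cols, drop = FALSE]
  meta$outlier <- as.logical(meta$outlier)
  spectra_table(as.matrix(df[, wl_cols, drop = FALSE]), wavelengths, meta)
}
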