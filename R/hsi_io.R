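#' Hyperspectral cube
#'
#' A 3-D array of digital numbers or reflectance with its wavelength grid and
#' acquisition metadata. Dimensions are `[rows, cols, bands]` where rows run
#' along the scan direction and cols across the sensor line.
#'
#' @param data Numeric 3-D array `[rows, cols, bands]`.
#' @param wavelengths Strictly increasing numeric vector, one value per band,
#'   in nm.
#' @param kind Either `"raw"` (digital numbers) or `"reflectance"`.
#' @param meta Named list of acquisition metadata (sample id, treatment, DAT,
#'   round, ...). Carried unchanged through I/O and calibration.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavelengths, kind = c("raw", "reflectance"),
                       meta = list()) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3-D array [rows, cols, bands]")
  }
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths)) {
    stop("band dimension (", dim(data)[3], ") does not match wavelength ",
         "count (", length(wavelengths), ")")
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (kind == "reflectance" && !all(is.finite(data))) {
    stop("reflectance cube contains non-finite values")
  }
  structure(list(data = data, wavelengths = wavelengths, kind = kind,
                 meta = meta),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind=%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' Dark/white reference frames
#'
#' Flat-field references for a line-scan camera. Each reference is either a
#' scalar, a `[cols, bands]` matrix (one spatial line, broadcast along the
#' scan direction) or a full `[rows, cols, bands]` array conformable with the
#' cube.
#'
#' @param dark,white Numeric scalar, matrix or array as above.
#' @return An object of class `reference_frames`.
#' @export
reference_frames <- function(dark, white) {
  structure(list(dark = dark, white = white), class = "reference_frames")
}

# Broadcast a reference (scalar / [cols,bands] matrix / full array) to one
# band slice of shape [rows, cols].
ref_slice <- function(ref, b, rows, cols) {
  if (length(ref) == 1L) {
    matrix(ref, rows, cols)
  } else if (is.matrix(ref)) {
    if (nrow(ref) != cols) {
      stop("reference matrix must be [cols x bands]; got ", nrow(ref),
           " rows for ", cols, " spatial columns")
    }
    matrix(ref[, b], nrow = rows, ncol = cols, byrow = TRUE)
  } else if (is.array(ref) && length(dim(ref)) == 3L) {
    ref[, , b]
  } else {
    stop("reference must be a scalar, a [cols x bands] matrix or a 3-D array")
  }
}

#' Flat-field reflectance calibration
#'
#' Converts raw digital numbers to relative reflectance against a flat
#' reference board: `R = (raw - dark) / (white - dark)`, elementwise. Values
#' outside `[0, 1]` are kept, not clipped (vegetation NIR reflectance can
#' exceed the board's and clipping would bias downstream scatter correction).
#'
#' @param raw A `raw`-kind [hyper_cube()].
#' @param refs A [reference_frames()] object conformable with the cube.
#' @param scale `"fraction"` (default) leaves reflectance as a fraction;
#'   `"percent"` multiplies by 100.
#' @return A `reflectance`-kind [hyper_cube()] with metadata preserved.
#' @export
calibrate <- function(raw, refs, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  stopifnot(inherits(raw, "hyper_cube"), inherits(refs, "reference_frames"))
  if (raw$kind != "raw") stop("cube is already calibrated")
  d <- dim(raw$data)
  out <- array(NA_real_, d)
  for (b in seq_len(d[3])) {
    dk <- ref_slice(refs$dark, b, d[1], d[2])
    wt <- ref_slice(refs$white, b, d[1], d[2])
    den <- wt - dk
    if (any(den <= 0)) {
      bad <- which(den <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "white - dark <= 0 at band %d (%.1f nm), pixel [%d, %d]",
        b, raw$wavelengths[b], bad[1], bad[2]))
    }
    out[, , b] <- (raw$data[, , b] - dk) / den
  }
  if (scale == "percent") out <- out * 100
  hyper_cube(out, raw$wavelengths, kind = "reflectance", meta = raw$meta)
}

envi_dtype <- function(code) {
  switch(as.character(code),
         "1"  = list(what = "integer", size = 1L, signed = FALSE),
         "2"  = list(what = "integer", size = 2L, signed = TRUE),
         "3"  = list(what = "integer", size = 4L, signed = TRUE),
         "4"  = list(what = "numeric", size = 4L, signed = TRUE),
         "5"  = list(what = "numeric", size = 8L, signed = TRUE),
         "12" = list(what = "integer", size = 2L, signed = FALSE),
         stop("unsupported ENVI data type: ", code))
}

#' Write a cube in ENVI format
#'
#' Emits the binary image file at `path` and a text header at `path.hdr`
#' carrying dimensions, interleave, data type, byte order and the wavelength
#' list.
#'
#' @param cube A [hyper_cube()].
#' @param path Output path for the binary image (header written alongside).
#' @param interleave One of `"bil"`, `"bsq"`, `"bip"`.
#' @param data_type ENVI data-type code: 4 (float32), 5 (float64, default;
#'   lossless for R doubles), 1/2/12 for integer cubes.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq", "bip"),
                       data_type = 5) {
  interleave <- match.arg(interleave)
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  # R arrays are [rows(lines), cols(samples), bands]; permute so the ENVI
  # element order comes out with the first permuted dimension fastest.
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),   # sample, line, band
                 bil = c(2, 3, 1),   # sample, band, line
                 bip = c(3, 2, 1))   # band, sample, line
  vec <- as.vector(aperm(cube$data, perm))
  dt <- envi_dtype(data_type)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vec)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vec), con, size = dt$size, endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = {hsisoa exported cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("kind = %s", cube$kind),
    sprintf("wavelength units = nm"),
    sprintf("wavelength = {%s}",
            paste(formatC(cube$wavelengths, format = "f", digits = 4),
                  collapse = ", "))
  )
  scalar <- vapply(cube$meta, function(v) length(v) == 1, logical(1))
  if (any(scalar)) {
    hdr <- c(hdr, sprintf("meta %s = %s", names(cube$meta)[scalar],
                          vapply(cube$meta[scalar], as.character,
                                 character(1))))
  }
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_field <- function(name, required = TRUE) {
    pat <- paste0("(?mi)^\\s*", name, "\\s*=\\s*([^\\{\\n]+)$")
    m <- regmatches(txt, regexec(pat, txt, perl = TRUE))[[1]]
    if (length(m) < 2) {
      if (required) stop("ENVI header missing field: ", name)
      return(NA_character_)
    }
    trimws(m[2])
  }
  get_block <- function(name) {
    pat <- paste0("(?si)", name, "\\s*=\\s*\\{([^}]*)\\}")
    m <- regmatches(txt, regexec(pat, txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(m[2], "[,\n]")[[1]])
  }
  list(
    samples = as.integer(get_field("samples")),
    lines = as.integer(get_field("lines")),
    bands = as.integer(get_field("bands")),
    data_type = as.integer(get_field("data type")),
    interleave = tolower(get_field("interleave")),
    byte_order = as.integer(get_field("byte order")),
    kind = {
      k <- get_field("kind", required = FALSE)
      if (is.na(k)) "raw" else k
    },
    wavelength = get_block("wavelength"),
    meta = {
      mm <- regmatches(lines, regexec("^meta ([^=]+)=(.*)$", lines))
      mm <- mm[vapply(mm, length, integer(1)) == 3]
      vals <- lapply(mm, function(m) {
        v <- trimws(m[3])
        if (!is.na(suppressWarnings(as.numeric(v)))) as.numeric(v) else v
      })
      stats::setNames(vals, trimws(vapply(mm, `[`, character(1), 2)))
    }
  )
}

#' Read an ENVI cube
#'
#' @param path Path to the binary image file; the header is looked up at
#'   `path.hdr` (or `path` with the extension replaced by `.hdr`).
#' @return A [hyper_cube()].
#' @export
read_envi <- function(path) {
  hdr_path <- if (file.exists(paste0(path, ".hdr"))) {
    paste0(path, ".hdr")
  } else {
    sub("\\.[^.]+$", ".hdr", path)
  }
  if (!file.exists(hdr_path)) stop("ENVI header not found for ", path)
  h <- parse_envi_header(hdr_path)
  if (is.null(h$wavelength)) stop("ENVI header missing wavelength block")
  if (length(h$wavelength) != h$bands) {
    stop("ENVI header declares ", h$bands, " bands but lists ",
         length(h$wavelength), " wavelengths")
  }
  if (!h$interleave %in% c("bil", "bsq", "bip")) {
    stop("unsupported interleave: ", h$interleave)
  }
  dt <- envi_dtype(h$data_type)
  n <- h$samples * h$lines * h$bands
  expected_bytes <- n * dt$size
  actual_bytes <- file.info(path)$size
  if (is.na(actual_bytes) || actual_bytes < expected_bytes) {
    stop("ENVI data file smaller than header dimensions imply (",
         actual_bytes, " < ", expected_bytes, " bytes)")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vec <- if (dt$what == "integer") {
    as.numeric(readBin(con, integer(), n = n, size = dt$size,
                       signed = dt$signed, endian = "little"))
  } else {
    readBin(con, numeric(), n = n, size = dt$size, endian = "little")
  }
  dims <- switch(h$interleave,
                 bsq = c(h$samples, h$lines, h$bands),
                 bil = c(h$samples, h$bands, h$lines),
                 bip = c(h$bands, h$samples, h$lines))
  arr <- array(vec, dims)
  data <- switch(h$interleave,
                 bsq = aperm(arr, c(2, 1, 3)),
                 bil = aperm(arr, c(3, 1, 2)),
                 bip = aperm(arr, c(3, 2, 1)))
  kind <- if (identical(h$kind, "reflectance")) "reflectance" else "raw"
  hyper_cube(data, h$wavelength, kind = kind,
             meta = if (length(h$meta)) h$meta else list())
}
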