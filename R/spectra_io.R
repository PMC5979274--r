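#' Read a two-column wavenumber/absorbance CSV
#'
#' Reads one instrument-exported spectrum. The dialect is comma-separated
#' with wavenumber in the first column and absorbance in the second; a
#' single header line is optional; row order (ascending or descending
#' wavenumber) is irrelevant because the returned object is canonicalised
#' to ascending order.
#'
#' @param path file path.
#' @param genotype,sample_id,subsample_id design labels attached to the
#'   spectrum.
#' @return An [IRSpectrum-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("1000,0.1", "1002,0.2", "1004,0.1"), f)
#' \dontshow{s <- readSpectrumCSV(f, "WT", "W1", "1")}
#' @export
readSpectrumCSV <- function(path, genotype = "NA", sample_id = "NA",
                            subsample_id = "1") {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  first <- strsplit(lines[[1L]], ",")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first[1:2]))))
  data_lines <- if (has_header) lines[-1L] else lines
  offset <- if (has_header) 1L else 0L
  parts <- strsplit(data_lines, ",")
  n <- length(parts)
  w <- numeric(n)
  a <- numeric(n)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) < 2L)
      stop(sprintf("line %d of %s: fewer than 2 columns", i + offset, path))
    vals <- suppressWarnings(as.numeric(p[1:2]))
    if (any(is.na(vals)))
      stop(sprintf("line %d of %s: non-numeric value", i + offset, path))
    w[i] <- vals[1L]
    a[i] <- vals[2L]
  }
  if (n < 8L)
    stop(sprintf("degenerate spectrum in %s: only %d points (need >= 8)",
                 path, n))
  IRSpectrum(w, a, genotype, sample_id, subsample_id)
}

#' Write a spectrum as a two-column CSV
#'
#' Writes the dialect read by [readSpectrumCSV()] (header line
#' `wavenumber,absorbance`, ascending wavenumber).
#'
#' @param s an [IRSpectrum-class].
#' @param path destination file.
#' @param overwrite overwrite an existing file?
#' @return `path`, invisibly.
#' @export
writeSpectrumCSV <- function(s, path, overwrite = FALSE) {
  stopifnot(is(s, "IRSpectrum"))
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path)
  writeLines(
    c("wavenumber,absorbance",
      sprintf("%.10g,%.12g", s@wavenumbers, s@absorbance)),
    path
  )
  invisible(path)
}

#' Read a JCAMP-DX spectrum (AFFN XYDATA)
#'
#' Minimal convenience reader for JCAMP-DX files whose `##XYDATA=(X++(Y..Y))`
#' block is written in plain fixed-point (AFFN) form: each data line holds
#' one X value followed by one or more Y values at `##DELTAX` spacing.
#' `##XFACTOR`/`##YFACTOR` are applied. Compressed (SQZ/DIF/DUP) encodings
#' are not supported.
#'
#' @inheritParams readSpectrumCSV
#' @return An [IRSpectrum-class].
#' @export
readJCAMPDX <- function(path, genotype = "NA", sample_id = "NA",
                        subsample_id = "1") {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  getfield <- function(key, default = NA_real_) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^##", key, "="), "", hit[[1L]], ignore.case = TRUE))
  }
  xfac <- getfield("XFACTOR", 1)
  yfac <- getfield("YFACTOR", 1)
  deltax <- getfield("DELTAX")
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA block in ", path)
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- if (length(end)) min(end[end > start[1L]]) else length(lines) + 1L
  body <- lines[(start[1L] + 1L):(end - 1L)]
  body <- body[nzchar(trimws(body)) & !grepl("^##", body)]
  w <- numeric(0)
  a <- numeric(0)
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]]))
    if (any(is.na(vals)))
      stop("non-AFFN data line in ", path, ": ", ln)
    x0 <- vals[1L] * xfac
    ys <- vals[-1L] * yfac
    if (length(ys) > 1L && is.na(deltax))
      stop("multiple Y per line require ##DELTAX in ", path)
    step <- if (is.na(deltax)) 0 else deltax * xfac
    w <- c(w, x0 + step * (seq_along(ys) - 1L))
    a <- c(a, ys)
  }
  if (length(w) < 8L)
    stop(sprintf("degenerate spectrum in %s: only %d points (need >= 8)",
                 path, length(w)))
  IRSpectrum(w, a, genotype, sample_id, subsample_id)
}

#' Interpolate spectra onto one shared wavenumber grid
#'
#' Linearly interpolates every spectrum onto a common grid so that
#' Euclidean distances between spectra (and column-wise statistics) are
#' defined. The grid spans the intersection of all spectra's supports (or
#' the requested `range`) at the requested spacing; values at coinciding
#' nodes are preserved exactly. Aligning an already-aligned set is the
#' identity.
#'
#' @param x a list of [IRSpectrum-class] objects or an [IRSpectrumSet-class].
#' @param spacing grid spacing in cm^-1 (default 2, typical for instruments
#'   run at 4 cm^-1 optical resolution).
#' @param range optional `c(low, high)` bounds in cm^-1; must be covered by
#'   every spectrum.
#' @return An [IRSpectrumSet-class] on the shared grid.
#' @export
alignToGrid <- function(x, spacing = 2, range = NULL) {
  spectra <- if (is(x, "IRSpectrumSet")) {
    lapply(seq_len(ncol(x)), function(i) getSpectrum(x, i))
  } else {
    x
  }
  stopifnot(length(spectra) > 0L)
  lows <- vapply(spectra, function(s) min(s@wavenumbers), numeric(1))
  highs <- vapply(spectra, function(s) max(s@wavenumbers), numeric(1))
  if (is.null(range)) {
    lo <- max(lows)
    hi <- min(highs)
  } else {
    lo <- min(range)
    hi <- max(range)
    bad <- which(lows > lo + 1e-9 | highs < hi - 1e-9)
    if (length(bad)) {
      s <- spectra[[bad[1L]]]
      stop(sprintf(
        "spectrum %s/%s/%s does not cover the requested range %.1f-%.1f cm-1",
        s@genotype, s@sample_id, s@subsample_id, lo, hi
      ))
    }
  }
  if (hi <= lo) stop("spectra have no common wavenumber range")
  grid <- seq(lo, hi, by = spacing)
  aligned <- lapply(spectra, function(s) {
    if (length(s@wavenumbers) == length(grid) &&
        isTRUE(all.equal(s@wavenumbers, grid, tolerance = 1e-9)))
      return(s)
    a <- approx(s@wavenumbers, s@absorbance, xout = grid, method = "linear",
                rule = 1)$y
    IRSpectrum(grid, a, s@genotype, s@sample_id, s@subsample_id)
  })
  IRSpectrumSet(aligned)
}

#' Read a directory of spectrum CSVs into a set
#'
#' File names are expected as `<genotype>_<sample>_<subsample>.csv` (the
#' layout written by [writeSpectrumSet()]); spectra are aligned onto a
#' shared grid.
#'
#' @param dir directory of per-spectrum CSV files.
#' @param spacing grid spacing passed to [alignToGrid()].
#' @return An [IRSpectrumSet-class].
#' @export
readSpectrumDir <- function(dir, spacing = 2) {
  if (!dir.exists(dir)) stop("spectra directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no .csv spectra in ", dir)
  spectra <- lapply(files, function(f) {
    parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1L]]
    if (length(parts) < 3L)
      stop("cannot parse design labels from file name: ", basename(f))
    readSpectrumCSV(f, parts[1L], parts[2L], parts[3L])
  })
  alignToGrid(spectra, spacing = spacing)
}

#' Write a set as per-spectrum CSV files
#'
#' @param set an [IRSpectrumSet-class].
#' @param dir destination directory (created if absent).
#' @param overwrite overwrite existing files?
#' @return the directory, invisibly.
#' @export
writeSpectrumSet <- function(set, dir, overwrite = FALSE) {
  stopifnot(is(set, "IRSpectrumSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(ncol(set))) {
    s <- getSpectrum(set, i)
    f <- file.path(dir, sprintf("%s_%s_%s.csv", s@genotype, s@sample_id,
                                s@subsample_id))
    writeSpectrumCSV(s, f, overwrite = overwrite)
  }
  invisible(dir)
}

#' Write a feature table to CSV
#'
#' One row per (sample, subsample) observation, columns in the scheme's
#' declaration order. Values are written with 15 significant digits so a
#' write/read round trip is the identity to at least 12 significant digits.
#'
#' @param ft feature table data.frame from [extractFeatures()].
#' @param path destination file.
#' @param overwrite overwrite an existing file?
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path, overwrite = FALSE) {
  stopifnot(is.data.frame(ft), nrow(ft) > 0L)
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path)
  fmt <- ft
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.15g", x))
  write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path CSV file path.
#' @return data.frame with design columns as character, features numeric.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  ft <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("genotype", "sample_id", "subsample_id"))
    if (col %in% names(ft)) ft[[col]] <- as.character(ft[[col]])
  ft
}
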