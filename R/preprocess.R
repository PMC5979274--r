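#' Normalize a spectrum
#'
#' `minmax` rescales absorbance affinely so the minimum over the full
#' recorded range is 0 and the maximum is 1, removing the multiplicative
#' path-length/thickness artifacts of ATR contact; `offset` only subtracts
#' the minimum; `none` returns the spectrum unchanged.
#'
#' @param s an [IRSpectrum-class].
#' @param method `"minmax"` (default), `"offset"` or `"none"`.
#' @return A normalized [IRSpectrum-class].
#' @examples
#' s <- IRSpectrum(1:3, c(2, 4, 6))
#' absorbance(normalizeSpectrum(s))  # 0, 0.5, 1
#' @export
normalizeSpectrum <- function(s, method = c("minmax", "offset", "none")) {
  stopifnot(is(s, "IRSpectrum"))
  method <- match.arg(method)
  a <- s@absorbance
  a <- switch(method,
    minmax = {
      rng <- max(a) - min(a)
      if (rng <= 0)
        stop(sprintf(
          "constant spectrum %s/%s/%s cannot be min-max normalized",
          s@genotype, s@sample_id, s@subsample_id))
      (a - min(a)) / rng
    },
    offset = a - min(a),
    none = a
  )
  initialize(s, absorbance = a)
}

#' Normalize every spectrum in a set
#'
#' @param set an [IRSpectrumSet-class].
#' @inheritParams normalizeSpectrum
#' @return An [IRSpectrumSet-class].
#' @export
normalizeSet <- function(set, method = c("minmax", "offset", "none")) {
  stopifnot(is(set, "IRSpectrumSet"))
  method <- match.arg(method)
  if (method == "none") return(set)
  mat <- absorbance(set)
  mat <- apply(mat, 2L, function(a) {
    if (method == "minmax") {
      rng <- max(a) - min(a)
      if (rng <= 0) stop("constant spectrum cannot be min-max normalized")
      (a - min(a)) / rng
    } else {
      a - min(a)
    }
  })
  out <- set
  SummarizedExperiment::assay(out, "absorbance") <- mat
  out
}

#' Auto-smoothed second derivative of a spectrum
#'
#' Savitzky-Golay smoothed second derivative: a local polynomial of order
#' `polyorder` is fit in a sliding window of `window` points and its second
#' derivative evaluated at the centre, scaled by the grid spacing so values
#' are in absorbance per cm^-1 squared. Absorption bands appear as minima,
#' and any straight-line baseline contribution vanishes (for
#' `polyorder >= 2`), which is what lets the derivative resolve overlapped
#' peaks riding on sloped baselines.
#'
#' @param s an [IRSpectrum-class] on an (approximately) even grid.
#' @param window odd window length in points (default 9).
#' @param polyorder polynomial order, `>= 2` and `< window` (default 3).
#' @return An [IRDerivative-class] on the parent grid.
#' @export
secondDerivative <- function(s, window = 9L, polyorder = 3L) {
  stopifnot(is(s, "IRSpectrum"))
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (polyorder < 2L) stop("polyorder must be >= 2 for a second derivative")
  n <- length(s@wavenumbers)
  if (window > n) stop("window exceeds spectrum length")
  h <- mean(diff(s@wavenumbers))
  d2 <- signal::sgolayfilt(s@absorbance, p = polyorder, n = window, m = 2L,
                           ts = h)
  new("IRDerivative",
    wavenumbers = s@wavenumbers,
    values = as.numeric(d2),
    window = window,
    polyorder = polyorder,
    parent_id = paste(s@genotype, s@sample_id, s@subsample_id, sep = "/")
  )
}
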