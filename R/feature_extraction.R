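## Region arguments throughout accept either a numeric length-2 vector of
## baseline endpoints (any order) or a one-row data.frame with high/low
## columns (a row of schemeRegions()).

.regionBounds <- function(region) {
  if (is.data.frame(region)) {
    c(high = as.numeric(region$high[1L]), low = as.numeric(region$low[1L]))
  } else {
    r <- as.numeric(region)
    stopifnot(length(r) == 2L)
    c(high = max(r), low = min(r))
  }
}

.nearestNode <- function(w, at) which.min(abs(w - at))

## indices of the grid nodes spanning a region, endpoints snapped to the
## nearest node ("ca." wavenumbers)
.regionIndex <- function(s, region) {
  b <- .regionBounds(region)
  w <- s@wavenumbers
  if (b["low"] < min(w) - 1e-9 || b["high"] > max(w) + 1e-9)
    stop(sprintf("region %.0f-%.0f cm-1 outside the spectrum grid (%.1f-%.1f)",
                 b["high"], b["low"], min(w), max(w)))
  i1 <- .nearestNode(w, b["low"])
  i2 <- .nearestNode(w, b["high"])
  if (i2 <= i1) stop("degenerate region: fewer than 2 grid nodes")
  i1:i2
}

#' Two-point linear baseline of a region
#'
#' The baseline of a region is the straight line joining the spectrum's
#' absorbance at the grid nodes nearest the region's two endpoints. This is
#' the height "below the baseline" subtracted from every peak height and
#' area in that region.
#'
#' @param s an [IRSpectrum-class].
#' @param region baseline endpoints: numeric `c(high, low)` in cm^-1 or a
#'   one-row data.frame from [schemeRegions()].
#' @param at wavenumber(s) at which to evaluate the baseline; must lie
#'   inside the region.
#' @return baseline absorbance at `at`.
#' @export
baselineValue <- function(s, region, at) {
  stopifnot(is(s, "IRSpectrum"))
  idx <- .regionIndex(s, region)
  w <- s@wavenumbers
  a <- s@absorbance
  w1 <- w[idx[1L]]
  w2 <- w[idx[length(idx)]]
  if (any(at < w1 - 1e-9) || any(at > w2 + 1e-9))
    stop(sprintf("wavenumber outside region %.1f-%.1f cm-1", w2, w1))
  a1 <- a[idx[1L]]
  a2 <- a[idx[length(idx)]]
  a1 + (a2 - a1) * (at - w1) / (w2 - w1)
}

#' Locate a peak within its search window
#'
#' In `apex` mode the peak is the wavenumber of maximum absorbance inside
#' the window `nominal +/- halfwidth`; in `second_derivative` mode it is
#' the minimum of the smoothed second derivative, which resolves bands that
#' visually merge in the absorbance trace. When the extremum falls on the
#' window edge (no interior extremum, e.g. a flat or monotone stretch), the
#' nominal position is returned; exact ties break toward the nominal
#' position.
#'
#' @param s an [IRSpectrum-class].
#' @param d2 the matching [IRDerivative-class] (required for
#'   `second_derivative` mode).
#' @param nominal nominal peak position (cm^-1).
#' @param mode `"apex"` or `"second_derivative"`.
#' @param halfwidth search half-width in cm^-1 (default 8).
#' @return located peak wavenumber (a grid node, or `nominal` as fallback).
#' @export
locatePeak <- function(s, d2 = NULL, nominal,
                       mode = c("apex", "second_derivative"),
                       halfwidth = 8) {
  stopifnot(is(s, "IRSpectrum"))
  mode <- match.arg(mode)
  w <- s@wavenumbers
  if (nominal - halfwidth < min(w) - 1e-9 ||
      nominal + halfwidth > max(w) + 1e-9)
    stop(sprintf("search window %.0f +/- %.0f cm-1 outside the grid",
                 nominal, halfwidth))
  win <- which(w >= nominal - halfwidth & w <= nominal + halfwidth)
  y <- if (mode == "apex") {
    s@absorbance[win]
  } else {
    if (is.null(d2)) stop("second_derivative mode requires a d2 spectrum")
    if (!isTRUE(all.equal(d2@wavenumbers, w, tolerance = 1e-9)))
      stop("d2 must share the spectrum's grid")
    -d2@values[win]
  }
  best <- which(y >= max(y) - 1e-15)
  if (length(best) > 1L)  # ties break toward the nominal position
    best <- best[which.min(abs(w[win][best] - nominal))]
  if (best == 1L || best == length(win)) return(nominal)
  w[win[best]]
}

#' Baseline-corrected peak height
#'
#' Absorbance at `at` minus the region baseline there. Corrected heights
#' may be negative (a band sitting below the local baseline); they are
#' reported as-is with a warning rather than clipped, so downstream group
#' statistics remain unbiased.
#'
#' @inheritParams baselineValue
#' @return corrected height (absorbance units).
#' @export
correctedHeight <- function(s, region, at) {
  h <- s@absorbance[.nearestNode(s@wavenumbers, at)] -
    baselineValue(s, region, at)
  if (any(h < 0))
    warning(sprintf("negative corrected height at %.0f cm-1 (%s/%s/%s)",
                    at[which(h < 0)[1L]], s@genotype, s@sample_id,
                    s@subsample_id))
  h
}

.trapz <- function(x, y) pracma::trapz(x, y)

#' Baseline-corrected trapezoidal region area
#'
#' Cumulative trapezoid of the spectrum between every two adjacent grid
#' nodes across the region, minus the trapezoid of the two-point linear
#' baseline — equivalently the trapezoid of (spectrum - baseline). Lobes
#' below the baseline contribute negatively (signed, not clipped).
#'
#' @inheritParams baselineValue
#' @return corrected area (absorbance x cm^-1).
#' @export
correctedArea <- function(s, region) {
  stopifnot(is(s, "IRSpectrum"))
  idx <- .regionIndex(s, region)
  w <- s@wavenumbers[idx]
  a <- s@absorbance[idx]
  bl <- baselineValue(s, region, w)
  .trapz(w, a - bl)
}

#' Split a region's corrected area at a wavenumber
#'
#' Both parts are measured against the parent region's single baseline and
#' cut at the grid node nearest `split_at`, so they are exactly additive:
#' high-side part + low-side part = whole-region area.
#'
#' @inheritParams baselineValue
#' @param split_at cut wavenumber, strictly inside the region.
#' @return named numeric length 2: `high` (above the cut) and `low` parts.
#' @export
splitArea <- function(s, region, split_at) {
  stopifnot(is(s, "IRSpectrum"))
  idx <- .regionIndex(s, region)
  w <- s@wavenumbers[idx]
  if (split_at <= w[1L] || split_at >= w[length(w)])
    stop("split point must lie strictly inside the region")
  cut <- .nearestNode(w, split_at)
  a <- s@absorbance[idx]
  bl <- baselineValue(s, region, w)
  resid <- a - bl
  c(high = .trapz(w[cut:length(w)], resid[cut:length(w)]),
    low = .trapz(w[1:cut], resid[1:cut]))
}

#' Append ratio features to feature-table rows
#'
#' Ratios are computed per observation (per subsample row), before any
#' averaging, matching the observation-level statistical model; a
#' denominator at or below 1e-12 yields NA with a warning.
#'
#' @param row data.frame of feature-table rows containing all operands.
#' @param scheme a [RegionScheme-class].
#' @return `row` with one appended column per declared ratio.
#' @export
computeRatios <- function(row, scheme) {
  stopifnot(is.data.frame(row))
  rt <- scheme@ratios
  for (i in seq_len(nrow(rt))) {
    num <- row[[rt$numerator[i]]]
    den <- row[[rt$denominator[i]]]
    if (is.null(num) || is.null(den))
      stop("ratio ", rt$name[i], ": operand missing from table")
    bad <- !is.na(den) & abs(den) <= 1e-12
    if (any(bad)) {
      warning("ratio ", rt$name[i], ": denominator ~ 0, set to NA")
      den[bad] <- NA_real_
    }
    row[[rt$name[i]]] <- num / den
  }
  row
}

## All scheme features for one preprocessed spectrum -> named numeric row.
.spectrumFeatures <- function(s, d2, scheme, locate = TRUE) {
  pk <- scheme@peaks
  rg <- scheme@regions
  vals <- numeric(0)
  for (i in seq_len(nrow(pk))) {
    region <- rg[rg$name == pk$region[i], , drop = FALSE]
    at <- if (locate) {
      locatePeak(s, d2, pk$nominal[i], pk$mode[i], pk$search_halfwidth[i])
    } else {
      pk$nominal[i]
    }
    vals[pk$name[i]] <- suppressWarnings(correctedHeight(s, region, at))
  }
  for (i in seq_len(nrow(rg))) {
    if (is.na(rg$area_name[i])) next
    vals[rg$area_name[i]] <- correctedArea(s, rg[i, , drop = FALSE])
  }
  sp <- scheme@splits
  for (i in seq_len(nrow(sp))) {
    region <- rg[rg$name == sp$region[i], , drop = FALSE]
    parts <- splitArea(s, region, sp$split_at[i])
    vals[sp$part_high[i]] <- parts[["high"]]
    vals[sp$part_low[i]] <- parts[["low"]]
  }
  vals
}

#' Extract the full feature table from a spectrum set
#'
#' For every spectrum: normalize, take the auto-smoothed second
#' derivative, locate every scheme peak, and measure baseline-corrected
#' heights, region areas, split areas and per-observation ratios. The
#' result has one row per (genotype, sample, subsample) spectrum and one
#' column per feature, in scheme declaration order. A spectrum that fails
#' yields a row of NAs and a warning naming it; it does not abort the
#' batch. Deterministic given inputs and configuration.
#'
#' @param set an [IRSpectrumSet-class] on a shared grid.
#' @param scheme a [RegionScheme-class] (default [defaultAlfalfaScheme()]).
#' @param normalize normalization method, see [normalizeSpectrum()].
#' @param window,polyorder Savitzky-Golay parameters, see
#'   [secondDerivative()].
#' @param locate read heights at located peaks (default) or at the nominal
#'   wavenumbers (`locate = FALSE`).
#' @return data.frame: `genotype`, `sample_id`, `subsample_id`, then one
#'   numeric column per feature.
#' @export
extractFeatures <- function(set, scheme = defaultAlfalfaScheme(),
                            normalize = c("minmax", "offset", "none"),
                            window = 9L, polyorder = 3L, locate = TRUE) {
  stopifnot(is(set, "IRSpectrumSet"), is(scheme, "RegionScheme"))
  normalize <- match.arg(normalize)
  fn <- featureNames(scheme, with_ratios = FALSE)
  rows <- vector("list", ncol(set))
  for (i in seq_len(ncol(set))) {
    s <- getSpectrum(set, i)
    rows[[i]] <- tryCatch({
      sn <- normalizeSpectrum(s, normalize)
      d2 <- secondDerivative(sn, window, polyorder)
      .spectrumFeatures(sn, d2, scheme, locate = locate)
    }, error = function(e) {
      warning(sprintf("spectrum %s/%s/%s failed: %s", s@genotype,
                      s@sample_id, s@subsample_id, conditionMessage(e)))
      setNames(rep(NA_real_, length(fn)), fn)
    })
  }
  ft <- as.data.frame(do.call(rbind, rows))
  ft <- cbind(
    data.frame(genotype = genotype(set), sample_id = sampleId(set),
               subsample_id = subsampleId(set), stringsAsFactors = FALSE),
    ft
  )
  rownames(ft) <- NULL
  computeRatios(ft, scheme)
}
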