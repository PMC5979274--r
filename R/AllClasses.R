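#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx aggregate anova aov coef dist hclust prcomp
#'   quantile resid rnorm runif sd setNames shapiro.test var
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' One subsample absorbance spectrum
#'
#' A single ATR-FTIR absorbance trace on a strictly increasing wavenumber
#' grid, labelled with its position in the genotype > sample > subsample
#' sampling design. Wavenumbers are in reciprocal centimetres; absorbance is
#' dimensionless.
#'
#' @slot wavenumbers numeric, strictly increasing, finite (cm^-1).
#' @slot absorbance numeric, same length as `wavenumbers`, finite.
#' @slot genotype character(1) genotype label (e.g. `"WT"`).
#' @slot sample_id character(1) biological replicate id (e.g. `"H1"`).
#' @slot subsample_id character(1) technical subsample id (e.g. `"1"`).
#'
#' @seealso [readSpectrumCSV()], [IRSpectrumSet-class]
#' @export
setClass("IRSpectrum",
  representation(
    wavenumbers = "numeric",
    absorbance = "numeric",
    genotype = "character",
    sample_id = "character",
    subsample_id = "character"
  )
)

setValidity("IRSpectrum", function(object) {
  w <- object@wavenumbers
  a <- object@absorbance
  msg <- character()
  if (length(w) != length(a))
    msg <- c(msg, "wavenumbers and absorbance must have equal length")
  if (length(w) && (!all(is.finite(w)) || !all(is.finite(a))))
    msg <- c(msg, "wavenumbers and absorbance must be finite")
  if (length(w) > 1L && any(diff(w) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  for (s in c("genotype", "sample_id", "subsample_id"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("%s must be a single string", s))
  if (length(msg)) msg else TRUE
})

#' Construct an IRSpectrum
#'
#' Values are reordered into canonical ascending-wavenumber order, so
#' instrument files written high-to-low are accepted as-is.
#'
#' @param wavenumbers,absorbance numeric vectors of equal length.
#' @param genotype,sample_id,subsample_id design labels.
#' @return An [IRSpectrum-class] object.
#' @examples
#' s <- IRSpectrum(c(1004, 1000, 1002), c(0.1, 0.1, 0.2))
#' wavenumbers(s)
#' @export
IRSpectrum <- function(wavenumbers, absorbance, genotype = "NA",
                       sample_id = "NA", subsample_id = "1") {
  o <- order(wavenumbers)
  new("IRSpectrum",
    wavenumbers = as.numeric(wavenumbers[o]),
    absorbance = as.numeric(absorbance[o]),
    genotype = as.character(genotype),
    sample_id = as.character(sample_id),
    subsample_id = as.character(subsample_id)
  )
}

#' Auto-smoothed second-derivative spectrum
#'
#' Savitzky-Golay smoothed second derivative of an [IRSpectrum-class],
#' sharing its parent's wavenumber grid. Absorption bands appear as local
#' minima. Units are absorbance per cm^-1 squared.
#'
#' @slot wavenumbers numeric grid inherited from the parent.
#' @slot values numeric second-derivative values.
#' @slot window odd integer Savitzky-Golay window length (points).
#' @slot polyorder integer local polynomial order, `< window`.
#' @slot parent_id character(1) label identifying the source spectrum.
#' @export
setClass("IRDerivative",
  representation(
    wavenumbers = "numeric",
    values = "numeric",
    window = "integer",
    polyorder = "integer",
    parent_id = "character"
  )
)

setValidity("IRDerivative", function(object) {
  msg <- character()
  if (length(object@wavenumbers) != length(object@values))
    msg <- c(msg, "wavenumbers and values must have equal length")
  if (object@window %% 2L == 0L)
    msg <- c(msg, "window must be odd")
  if (object@polyorder >= object@window)
    msg <- c(msg, "polyorder must be smaller than window")
  if (length(msg)) msg else TRUE
})

#' Set of spectra sharing one wavenumber grid
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `absorbance` assay with wavenumbers as rows and subsample spectra as
#' columns. `colData` carries the `genotype`, `sample_id`, `subsample_id`
#' design labels; `rowData` carries the `wavenumber` grid. The
#' (genotype, sample_id, subsample_id) triples must be unique.
#'
#' @seealso [IRSpectrumSet()], [alignToGrid()], [extractFeatures()]
#' @export
setClass("IRSpectrumSet", contains = "SummarizedExperiment")

setValidity("IRSpectrumSet", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("genotype", "sample_id", "subsample_id")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  key <- paste(cd$genotype, cd$sample_id, cd$subsample_id, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "(genotype, sample_id, subsample_id) triples must be unique")
  if (!"wavenumber" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain a wavenumber column")
  else {
    w <- SummarizedExperiment::rowData(object)$wavenumber
    if (length(w) > 1L && any(diff(w) <= 0))
      msg <- c(msg, "wavenumber grid must be strictly increasing")
  }
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an 'absorbance' assay is required")
  if (length(msg)) msg else TRUE
})

#' Construct an IRSpectrumSet from spectra on a common grid
#'
#' All spectra must already share one wavenumber grid; use [alignToGrid()]
#' first when they do not (e.g. after reading heterogeneous instrument
#' exports).
#'
#' @param spectra list of [IRSpectrum-class] objects.
#' @return An [IRSpectrumSet-class].
#' @examples
#' s1 <- IRSpectrum(1:10, rnorm(10), "WT", "W1", "1")
#' s2 <- IRSpectrum(1:10, rnorm(10), "WT", "W1", "2")
#' sset <- IRSpectrumSet(list(s1, s2))
#' dim(sset)
#' @export
IRSpectrumSet <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) > 0L)
  grid <- spectra[[1L]]@wavenumbers
  for (s in spectra)
    if (length(s@wavenumbers) != length(grid) ||
        !isTRUE(all.equal(s@wavenumbers, grid, tolerance = 1e-9)))
      stop("all spectra must share one wavenumber grid; run alignToGrid() first")
  mat <- vapply(spectra, slot, numeric(length(grid)), "absorbance")
  cd <- S4Vectors::DataFrame(
    genotype = vapply(spectra, slot, character(1), "genotype"),
    sample_id = vapply(spectra, slot, character(1), "sample_id"),
    subsample_id = vapply(spectra, slot, character(1), "subsample_id")
  )
  colnames(mat) <- paste(cd$genotype, cd$sample_id, cd$subsample_id, sep = ".")
  rownames(cd) <- colnames(mat)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = mat),
    rowData = S4Vectors::DataFrame(wavenumber = grid),
    colData = cd
  )
  new("IRSpectrumSet", se)
}

#' Declarative spectral region scheme
#'
#' Tabular description of the baseline regions, nominal peak positions,
#' area splits and feature ratios used by [extractFeatures()]. Region
#' bounds are two-point linear-baseline endpoints in cm^-1; each peak
#' belongs to a region and is located either at the absorbance apex or at
#' the second-derivative minimum inside a search window around its nominal
#' position.
#'
#' @slot regions data.frame with columns `name`, `high`, `low`,
#'   `area_name` (NA when the region carries no area feature).
#' @slot peaks data.frame with columns `name`, `nominal`, `region`,
#'   `mode` (`"apex"` or `"second_derivative"`), `search_halfwidth`.
#' @slot splits data.frame with columns `name`, `region`, `split_at`,
#'   `part_high`, `part_low` (feature names of the high- and low-wavenumber
#'   parts).
#' @slot ratios data.frame with columns `name`, `numerator`, `denominator`.
#'
#' @seealso [defaultAlfalfaScheme()], [validateScheme()], [loadScheme()]
#' @export
setClass("RegionScheme",
  representation(
    regions = "data.frame",
    peaks = "data.frame",
    splits = "data.frame",
    ratios = "data.frame"
  )
)

setValidity("RegionScheme", function(object) {
  v <- validateScheme(object)
  if (length(v)) v else TRUE
})

#' Synthetic spectrum-set design
#'
#' Parameters of the synthetic band-mixture generator: Gaussian/Lorentzian
#' bands, per-genotype sample counts and band-amplitude multipliers, the
#' two-level noise model (sample random effect, subsample white noise) and
#' quadratic baseline drift.
#'
#' @slot bands data.frame with columns `name`, `center`, `sigma`,
#'   `amplitude`, `shape`.
#' @slot genotypes data.frame with columns `genotype`, `n_samples`.
#' @slot multipliers numeric matrix, genotypes x bands.
#' @slot subsamples integer subsample spectra per sample.
#' @slot sample_sd numeric SD of the multiplicative per-band sample random
#'   effect (relative units).
#' @slot noise_sd numeric SD of additive subsample white noise (absorbance).
#' @slot drift_sd numeric length-3 SDs of the quadratic baseline
#'   coefficients (constant, linear, quadratic over the scaled grid).
#' @slot grid numeric length-3: low bound, high bound, spacing (cm^-1).
#'
#' @seealso [defaultDesign()], [simulateSpectra()]
#' @export
setClass("SyntheticDesign",
  representation(
    bands = "data.frame",
    genotypes = "data.frame",
    multipliers = "matrix",
    subsamples = "integer",
    sample_sd = "numeric",
    noise_sd = "numeric",
    drift_sd = "numeric",
    grid = "numeric"
  )
)

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  b <- object@bands
  if (any(b$sigma <= 0)) msg <- c(msg, "band widths must be positive")
  if (any(b$amplitude < 0)) msg <- c(msg, "band amplitudes must be >= 0")
  if (!all(b$shape %in% c("gaussian", "lorentzian")))
    msg <- c(msg, "band shape must be gaussian or lorentzian")
  if (any(object@genotypes$n_samples < 1L))
    msg <- c(msg, "each genotype needs at least one sample")
  if (any(object@multipliers <= 0))
    msg <- c(msg, "multipliers must be positive")
  if (!identical(dim(object@multipliers),
                 c(nrow(object@genotypes), nrow(b))))
    msg <- c(msg, "multipliers must be a genotypes x bands matrix")
  if (object@sample_sd < 0 || object@noise_sd < 0 || any(object@drift_sd < 0))
    msg <- c(msg, "noise SDs must be >= 0")
  if (length(object@grid) != 3L || object@grid[2] <= object@grid[1] ||
      object@grid[3] <= 0)
    msg <- c(msg, "grid must be (low, high, spacing) with high > low")
  if (length(msg)) msg else TRUE
})

setMethod("show", "IRSpectrum", function(object) {
  w <- object@wavenumbers
  cat(sprintf(
    "IRSpectrum %s/%s/%s: %d points, %.1f-%.1f cm-1\n",
    object@genotype, object@sample_id, object@subsample_id,
    length(w), min(w), max(w)
  ))
})

setMethod("show", "IRDerivative", function(object) {
  cat(sprintf(
    "IRDerivative of %s: %d points, Savitzky-Golay window %d, order %d\n",
    object@parent_id, length(object@values), object@window, object@polyorder
  ))
})

setMethod("show", "IRSpectrumSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  w <- SummarizedExperiment::rowData(object)$wavenumber
  cat(sprintf(
    "IRSpectrumSet: %d spectra x %d wavenumbers (%.1f-%.1f cm-1)\n",
    ncol(object), nrow(object), min(w), max(w)
  ))
  tab <- table(cd$genotype[!duplicated(paste(cd$genotype, cd$sample_id))])
  cat("  samples per genotype:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "RegionScheme", function(object) {
  cat(sprintf(
    "RegionScheme: %d regions, %d peaks, %d splits, %d ratios\n",
    nrow(object@regions), nrow(object@peaks),
    nrow(object@splits), nrow(object@ratios)
  ))
})

setMethod("show", "SyntheticDesign", function(object) {
  g <- object@genotypes
  cat(sprintf(
    "SyntheticDesign: %d bands; %s; %d subsamples/sample; grid %.0f-%.0f by %g\n",
    nrow(object@bands),
    paste(sprintf("%s n=%d", g$genotype, g$n_samples), collapse = ", "),
    object@subsamples, object@grid[1], object@grid[2], object@grid[3]
  ))
})
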