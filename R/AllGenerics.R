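#' Accessors for spectrum objects
#'
#' `wavenumbers()` returns the cm^-1 grid, `absorbance()` the absorbance
#' values (a vector for an [IRSpectrum-class], the wavenumber-by-spectrum
#' matrix for an [IRSpectrumSet-class]); `genotype()`, `sampleId()` and
#' `subsampleId()` return design labels; `derivValues()` the values of an
#' [IRDerivative-class].
#'
#' @param x an `IRSpectrum`, `IRSpectrumSet` or `IRDerivative`.
#' @return numeric or character vectors as described.
#' @name spectrum-accessors
NULL

#' @rdname spectrum-accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname spectrum-accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname spectrum-accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @rdname spectrum-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname spectrum-accessors
#' @export
setGeneric("subsampleId", function(x) standardGeneric("subsampleId"))

#' @rdname spectrum-accessors
#' @export
setGeneric("derivValues", function(x) standardGeneric("derivValues"))

#' @rdname spectrum-accessors
#' @export
setMethod("wavenumbers", "IRSpectrum", function(x) x@wavenumbers)

#' @rdname spectrum-accessors
#' @export
setMethod("wavenumbers", "IRDerivative", function(x) x@wavenumbers)

#' @rdname spectrum-accessors
#' @export
setMethod("wavenumbers", "IRSpectrumSet", function(x)
  SummarizedExperiment::rowData(x)$wavenumber)

#' @rdname spectrum-accessors
#' @export
setMethod("absorbance", "IRSpectrum", function(x) x@absorbance)

#' @rdname spectrum-accessors
#' @export
setMethod("absorbance", "IRSpectrumSet", function(x)
  SummarizedExperiment::assay(x, "absorbance"))

#' @rdname spectrum-accessors
#' @export
setMethod("genotype", "IRSpectrum", function(x) x@genotype)

#' @rdname spectrum-accessors
#' @export
setMethod("genotype", "IRSpectrumSet", function(x)
  SummarizedExperiment::colData(x)$genotype)

#' @rdname spectrum-accessors
#' @export
setMethod("sampleId", "IRSpectrum", function(x) x@sample_id)

#' @rdname spectrum-accessors
#' @export
setMethod("sampleId", "IRSpectrumSet", function(x)
  SummarizedExperiment::colData(x)$sample_id)

#' @rdname spectrum-accessors
#' @export
setMethod("subsampleId", "IRSpectrum", function(x) x@subsample_id)

#' @rdname spectrum-accessors
#' @export
setMethod("subsampleId", "IRSpectrumSet", function(x)
  SummarizedExperiment::colData(x)$subsample_id)

#' @rdname spectrum-accessors
#' @export
setMethod("derivValues", "IRDerivative", function(x) x@values)

#' Extract one spectrum from a set
#'
#' @param x an [IRSpectrumSet-class].
#' @param i column index or name.
#' @return An [IRSpectrum-class].
#' @export
getSpectrum <- function(x, i) {
  stopifnot(is(x, "IRSpectrumSet"))
  cd <- SummarizedExperiment::colData(x)[i, , drop = FALSE]
  IRSpectrum(
    wavenumbers(x), absorbance(x)[, i],
    genotype = cd$genotype, sample_id = cd$sample_id,
    subsample_id = cd$subsample_id
  )
}

#' Accessors for RegionScheme components
#'
#' @param x a [RegionScheme-class].
#' @return the corresponding data.frame.
#' @name scheme-accessors
NULL

#' @rdname scheme-accessors
#' @export
setGeneric("schemeRegions", function(x) standardGeneric("schemeRegions"))

#' @rdname scheme-accessors
#' @export
setGeneric("schemePeaks", function(x) standardGeneric("schemePeaks"))

#' @rdname scheme-accessors
#' @export
setGeneric("schemeSplits", function(x) standardGeneric("schemeSplits"))

#' @rdname scheme-accessors
#' @export
setGeneric("schemeRatios", function(x) standardGeneric("schemeRatios"))

#' @rdname scheme-accessors
#' @export
setMethod("schemeRegions", "RegionScheme", function(x) x@regions)

#' @rdname scheme-accessors
#' @export
setMethod("schemePeaks", "RegionScheme", function(x) x@peaks)

#' @rdname scheme-accessors
#' @export
setMethod("schemeSplits", "RegionScheme", function(x) x@splits)

#' @rdname scheme-accessors
#' @export
setMethod("schemeRatios", "RegionScheme", function(x) x@ratios)

#' Look up a region definition by name
#'
#' @param scheme a [RegionScheme-class].
#' @param name region name.
#' @return one-row data.frame with `name`, `high`, `low`.
#' @export
getRegion <- function(scheme, name) {
  r <- scheme@regions[scheme@regions$name == name, , drop = FALSE]
  if (nrow(r) != 1L) stop("unknown region: ", name)
  r
}
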