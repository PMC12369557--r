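#' @import methods
#' @importFrom stats cor rnorm runif sd var cov
#' @importFrom utils count.fields
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' Accessor generics for spectral objects
#'
#' `wavenumbers()` returns the wavenumber grid in cm^-1 (descending),
#' `absorbance()` the samples-by-wavenumbers absorbance matrix,
#' `blendTarget()` the per-sample blending proportion of the analyte
#' component (% by mass), `brands()` the per-sample brand labels and
#' `sampleIDs()` the unique per-sample identifiers.
#'
#' @param x a [SpectralSet] or [ComponentLibrary] object.
#' @return `wavenumbers()`: numeric vector; `absorbance()`: numeric matrix
#'   (n samples x d wavenumbers); `blendTarget()`: numeric vector in
#'   \[0, 100\]; `brands()`: character vector; `sampleIDs()`: character
#'   vector.
#' @name spectral-accessors
#' @aliases wavenumbers absorbance blendTarget brands sampleIDs
#' @examples
#' ds <- exampleSpectralSet()
#' length(wavenumbers(ds)) == ncol(absorbance(ds))
NULL

#' @rdname spectral-accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname spectral-accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname spectral-accessors
#' @export
setGeneric("blendTarget", function(x) standardGeneric("blendTarget"))

#' @rdname spectral-accessors
#' @export
setGeneric("brands", function(x) standardGeneric("brands"))

#' @rdname spectral-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
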