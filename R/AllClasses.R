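#' SpectralSet: NIR spectra with blending-proportion labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay,
#' `"absorbance"`, with wavenumbers as rows (descending cm^-1 grid stored in
#' `rowData(x)$wavenumber`) and samples as columns.  Column metadata carries
#' the per-sample `brand` label and the `target` blending proportion of the
#' analyte component in percent of total mass; column names are the unique
#' sample identifiers.
#'
#' Validity enforces the package's grid convention: strictly descending
#' wavenumbers, all-finite absorbance, targets inside \[0, 100\], and unique
#' sample IDs.
#'
#' @seealso [SpectralSet()] for construction, [readSpectra()] /
#'   [writeSpectra()] for the on-disk format.
#' @export
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
    msg <- character()
    w <- SummarizedExperiment::rowData(object)$wavenumber
    if (is.null(w))
        return("rowData must contain a 'wavenumber' column")
    if (length(w) && any(!is.finite(w)))
        msg <- c(msg, "wavenumbers must be finite")
    if (length(w) > 1L && any(diff(w) >= 0))
        msg <- c(msg, "wavenumbers must be strictly descending (cm^-1)")
    if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'absorbance' is required")
    else if (any(!is.finite(SummarizedExperiment::assay(object, "absorbance"))))
        msg <- c(msg, "absorbance contains non-finite values")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("brand", "target") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'brand' and 'target'")
    else {
        y <- cd$target
        if (length(y) && (any(!is.finite(y)) || any(y < 0) || any(y > 100)))
            msg <- c(msg, "target values must lie in [0, 100]")
    }
    ids <- colnames(object)
    if (is.null(ids) && ncol(object) > 0L)
        msg <- c(msg, "sample IDs (colnames) are required")
    if (anyDuplicated(ids))
        msg <- c(msg, "sample IDs must be unique")
    if (length(msg)) msg else TRUE
})

#' ComponentLibrary: endmember spectra for Beer-Lambert mixing
#'
#' Holds one pure-component ("endmember") absorbance spectrum per raw
#' material on a shared wavenumber grid, together with the Gaussian band
#' parameters (center cm^-1, width cm^-1, amplitude) and baseline constant
#' that generated each spectrum.  Brand-specific analyte variants are stored
#' as additional endmembers named `"<component>@<variant>"`.
#'
#' @slot wavenumbers numeric, shared descending grid (cm^-1).
#' @slot endmembers named list of numeric spectra, all strictly positive.
#' @slot bandParams named list; per component a list with `baseline` and a
#'   `bands` data.frame (`center`, `width`, `amplitude`).
#' @seealso [makeComponentLibrary()]
#' @export
setClass("ComponentLibrary",
    representation(wavenumbers = "numeric", endmembers = "list",
                   bandParams = "list"))

setValidity("ComponentLibrary", function(object) {
    msg <- character()
    w <- object@wavenumbers
    if (!length(w)) msg <- c(msg, "empty wavenumber grid")
    if (length(w) > 1L && any(diff(w) >= 0))
        msg <- c(msg, "grid must be strictly descending")
    if (!length(object@endmembers) || is.null(names(object@endmembers)))
        msg <- c(msg, "endmembers must be a named, non-empty list")
    for (nm in names(object@endmembers)) {
        e <- object@endmembers[[nm]]
        if (length(e) != length(w))
            msg <- c(msg, sprintf("endmember '%s' is not on the grid", nm))
        else if (any(!is.finite(e)) || any(e <= 0))
            msg <- c(msg, sprintf("endmember '%s' must be strictly positive", nm))
    }
    if (length(msg)) msg else TRUE
})

#' BrandDesign: sampling design for one brand's blending ratios
#'
#' @slot brand character label.
#' @slot nSamples integer sample count.
#' @slot componentRanges named list of `c(min, max)` percent ranges; a
#'   component absent from the list receives exactly 0%.
#' @slot analyte name of the regression-target component (its percentage is
#'   the response); must appear in `componentRanges`.
#' @slot silkVariant identifier of a brand-specific analyte endmember
#'   (`""` = the shared endmember).
#' @seealso [brandDesign()], [defaultBrandDesigns()], [sampleBlendDesign()]
#' @export
setClass("BrandDesign",
    representation(brand = "character", nSamples = "integer",
                   componentRanges = "list", analyte = "character",
                   silkVariant = "character"))

setValidity("BrandDesign", function(object) {
    msg <- character()
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    rg <- object@componentRanges
    if (!length(rg) || is.null(names(rg)))
        msg <- c(msg, "componentRanges must be a named list")
    for (nm in names(rg)) {
        r <- rg[[nm]]
        if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
            r[1] < 0 || r[2] > 100)
            msg <- c(msg, sprintf("range for '%s' must be c(min, max) in [0, 100]", nm))
    }
    if (!object@analyte %in% names(rg))
        msg <- c(msg, "analyte must have a declared range")
    mins <- sum(vapply(rg, `[`, numeric(1), 1L))
    maxs <- sum(vapply(rg, `[`, numeric(1), 2L))
    if (mins > 100 + 1e-9 || maxs < 100 - 1e-9)
        msg <- c(msg, "infeasible design: component ranges cannot sum to 100%")
    if (length(msg)) msg else TRUE
})

#' DomainShift: instrument/brand-level spectral perturbation
#'
#' Parameterises the inter-brand domain shift applied on top of the linear
#' mixing model: an additive offset, a linear baseline tilt across the grid
#' (`slope`, absorbance per cm^-1, applied to `w - mean(w)`), a
#' multiplicative gain, and i.i.d. Gaussian measurement noise.
#'
#' @slot offset additive offset, absorbance units.
#' @slot slope baseline tilt, absorbance per cm^-1.
#' @slot gain multiplicative gain (> 0), unitless.
#' @slot noiseSD Gaussian noise standard deviation (>= 0), absorbance units.
#' @seealso [domainShift()], [synthesizeDataset()]
#' @export
setClass("DomainShift",
    representation(offset = "numeric", slope = "numeric", gain = "numeric",
                   noiseSD = "numeric"))

setValidity("DomainShift", function(object) {
    msg <- character()
    if (length(object@gain) != 1L || !is.finite(object@gain) || object@gain <= 0)
        msg <- c(msg, "gain must be a single positive number")
    if (length(object@noiseSD) != 1L || !is.finite(object@noiseSD) ||
        object@noiseSD < 0)
        msg <- c(msg, "noiseSD must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' PCAModel: mean-centered principal component diagnostics
#'
#' @slot meanSpectrum per-wavenumber mean of the training matrix.
#' @slot loadings d x k orthonormal loading matrix (sign-fixed: the
#'   largest-magnitude element of each column is positive).
#' @slot explainedVarianceRatio fraction of total variance per component,
#'   non-increasing, summing to <= 1.
#' @seealso [pcaFit()]
#' @export
setClass("PCAModel",
    representation(meanSpectrum = "numeric", loadings = "matrix",
                   explainedVarianceRatio = "numeric"))

#' PLSRModel: SIMPLS partial least squares regression model
#'
#' Prediction is affine: `yhat = yMean + (x - xMean) %*% coefficients`.
#'
#' @slot xMean per-feature mean of the calibration matrix.
#' @slot yMean mean of the calibration response (%).
#' @slot nLatent number of latent variables used.
#' @slot coefficients regression weight vector (length d) for `nLatent`
#'   components.
#' @slot coefficientPath d x nLatent matrix; column a holds the coefficient
#'   vector of the a-component model (SIMPLS is nested, so truncation of a
#'   larger model reproduces smaller ones).
#' @slot trainingMetrics list with `pearsonR` (R_c) and `rmse` (RMSEC, %).
#' @seealso [plsrFit()], [plsrPredict()]
#' @export
setClass("PLSRModel",
    representation(xMean = "numeric", yMean = "numeric", nLatent = "integer",
                   coefficients = "numeric", coefficientPath = "matrix",
                   trainingMetrics = "list"))

#' TCATransform: fitted primal transfer-component projection
#'
#' @slot projection d x m projection matrix W.
#' @slot combinedMean per-feature mean of the stacked source+target matrix
#'   used for centering.
#' @slot mu ridge regulariser of the domain-distance term.
#' @slot m subspace dimension.
#' @slot mmdBefore squared linear-kernel MMD between source and target in
#'   the original feature space.
#' @slot mmdAfter squared linear-kernel MMD after projection.
#' @slot mmdPCABaseline squared linear-kernel MMD after projecting onto the
#'   top-m PCA axes of the stacked data (the variance-only baseline the TCA
#'   objective must not exceed).
#' @seealso [tcaFit()], [tcaTransform()]
#' @export
setClass("TCATransform",
    representation(projection = "matrix", combinedMean = "numeric",
                   mu = "numeric", m = "integer", mmdBefore = "numeric",
                   mmdAfter = "numeric", mmdPCABaseline = "numeric"))

#' CoralTransform: fitted correlation-alignment recoloring map
#'
#' The source features are whitened by the (shrunk) source covariance and
#' recolored by the (shrunk) target covariance:
#' `A = Cs^{-1/2} %*% Ct^{1/2}` via symmetric eigendecompositions.
#'
#' @slot sourceMean,targetMean per-feature domain means.
#' @slot recolor d x d linear map A.
#' @slot lambda named numeric(2), shrinkage added to the diagonal of the
#'   source and target covariances (absorbance^2 units).
#' @slot meanMode `"match"` (center on source mean, recolor, add target
#'   mean) or `"none"` (recolor the raw features; classic covariance-only
#'   alignment).
#' @seealso [coralFit()], [coralTransform()]
#' @export
setClass("CoralTransform",
    representation(sourceMean = "numeric", targetMean = "numeric",
                   recolor = "matrix", lambda = "numeric",
                   meanMode = "character"))

#' TransferResult: metrics of one cross-brand transfer task
#'
#' @slot task list with `source`, `target`, `method`, `updatingFraction` and
#'   the hyperparameters used.
#' @slot calibration list with `pearsonR` (R_c) and `rmse` (RMSEC, %),
#'   computed in the (possibly transformed) space the model was fitted in.
#' @slot prediction list with `pearsonR` (R_p), `rmse` (RMSEP, %) and `mae`
#'   (MAE, %), computed on the target-domain prediction set.
#' @slot nSource,nTargetPredicted sample counts after any updating.
#' @slot chosenNLatent latent variables selected by cross-validation.
#' @seealso [runTransferTask()]
#' @export
setClass("TransferResult",
    representation(task = "list", calibration = "list", prediction = "list",
                   nSource = "integer", nTargetPredicted = "integer",
                   chosenNLatent = "integer"))

#' StudyReport: consolidated results of a multi-brand transfer study
#'
#' @slot pooled list of pooled-model metrics (all brands merged, sorted
#'   interleaved 2:1 split).
#' @slot tasks data.frame of per-task base results (one row per ordered
#'   brand pair x method) in the layout
#'   `source, target, method, R_c, RMSEC, R_p, RMSEP, MAE, n_latent`.
#' @slot sweeps data.frame of model-updating sweep results with an
#'   additional `fraction` column.
#' @slot config list: the resolved study configuration (fingerprint).
#' @slot seed integer master seed.
#' @seealso [runFullStudy()], [reportToJSON()], [writeStudyReport()]
#' @export
setClass("StudyReport",
    representation(pooled = "list", tasks = "data.frame",
                   sweeps = "data.frame", config = "list", seed = "integer"))
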