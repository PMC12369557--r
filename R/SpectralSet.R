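#' Construct a SpectralSet
#'
#' Bundles a wavenumber grid, an absorbance matrix and per-sample metadata
#' into a validated [SpectralSet-class] object.  An ascending grid is
#' accepted and reordered (columns permuted consistently) to the package's
#' descending convention with a notice.
#'
#' @param absorbance numeric matrix, n samples x d wavenumbers.
#' @param wavenumbers numeric vector of length d, strictly monotone (cm^-1).
#' @param target numeric vector of length n, blending proportion of the
#'   analyte component in \[0, 100\] (%).
#' @param brand character vector of length n (recycled if length 1).
#' @param sampleID character vector of n unique sample identifiers; default
#'   `"S1"..."Sn"`.
#' @return a [SpectralSet-class].
#' @examples
#' g <- defaultGrid(10000, 4000, 500)
#' ds <- SpectralSet(matrix(runif(3 * length(g)), 3), g,
#'                   target = c(70, 80, 90), brand = "B1")
#' dim(absorbance(ds))
#' @export
SpectralSet <- function(absorbance, wavenumbers, target, brand,
                        sampleID = NULL) {
    absorbance <- as.matrix(absorbance)
    n <- nrow(absorbance)
    if (ncol(absorbance) != length(wavenumbers))
        stop("absorbance has ", ncol(absorbance),
             " columns but the grid has ", length(wavenumbers), " points")
    if (length(wavenumbers) > 1L) {
        dw <- diff(wavenumbers)
        if (all(dw > 0)) {
            message("wavenumber grid is ascending; reordering to the ",
                    "descending convention")
            o <- rev(seq_along(wavenumbers))
            wavenumbers <- wavenumbers[o]
            absorbance <- absorbance[, o, drop = FALSE]
        } else if (!all(dw < 0))
            stop("wavenumber grid must be strictly monotone")
    }
    if (is.null(sampleID))
        sampleID <- if (n) paste0("S", seq_len(n)) else character()
    if (length(brand) == 1L) brand <- rep(brand, n)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(absorbance = t(absorbance)),
        rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
        colData = S4Vectors::DataFrame(brand = as.character(brand),
                                       target = as.numeric(target),
                                       row.names = as.character(sampleID)))
    new("SpectralSet", se)
}

#' A small example SpectralSet
#'
#' Five synthetic blended spectra on a coarse grid; used in documentation
#' examples.
#' @return a [SpectralSet-class] with 5 samples.
#' @export
exampleSpectralSet <- function() {
    g <- defaultGrid(10000, 4000, 200)
    lib <- makeComponentLibrary(g, seed = 1L)
    des <- brandDesign("B2", 5L,
                       list(tobacco_silk = c(75, 100),
                            fermented_cut_stem = c(0, 25)))
    synthesizeDataset(lib, des, domainShift(noiseSD = 0.015), seed = 1L)
}

#' @rdname spectral-accessors
#' @export
setMethod("wavenumbers", "SpectralSet", function(x)
    SummarizedExperiment::rowData(x)$wavenumber)

#' @rdname spectral-accessors
#' @export
setMethod("absorbance", "SpectralSet", function(x)
    t(SummarizedExperiment::assay(x, "absorbance")))

#' @rdname spectral-accessors
#' @export
setMethod("blendTarget", "SpectralSet", function(x)
    SummarizedExperiment::colData(x)$target)

#' @rdname spectral-accessors
#' @export
setMethod("brands", "SpectralSet", function(x)
    SummarizedExperiment::colData(x)$brand)

#' @rdname spectral-accessors
#' @export
setMethod("sampleIDs", "SpectralSet", function(x) colnames(x))

setMethod("show", "SpectralSet", function(object) {
    w <- wavenumbers(object)
    cat("SpectralSet:", ncol(object), "samples x", nrow(object),
        "wavenumbers\n")
    if (length(w))
        cat(sprintf("  grid: %.0f .. %.0f cm^-1 (descending)\n",
                    w[1], w[length(w)]))
    b <- table(brands(object))
    if (length(b))
        cat("  brands:", paste(sprintf("%s (%d)", names(b), b),
                               collapse = ", "), "\n")
    y <- blendTarget(object)
    if (length(y))
        cat(sprintf("  target: %.2f .. %.2f %%\n", min(y), max(y)))
})

#' @rdname spectral-accessors
#' @export
setMethod("wavenumbers", "ComponentLibrary", function(x) x@wavenumbers)

setMethod("show", "ComponentLibrary", function(object) {
    cat("ComponentLibrary:", length(object@endmembers), "endmembers on",
        length(object@wavenumbers), "grid points\n")
    cat("  components:", paste(names(object@endmembers), collapse = ", "),
        "\n")
})

setMethod("show", "PLSRModel", function(object) {
    cat("PLSRModel:", object@nLatent, "latent variables,",
        length(object@coefficients), "features\n")
    tm <- object@trainingMetrics
    cat(sprintf("  calibration: R_c = %.4f, RMSEC = %.3f%%\n",
                tm$pearsonR, tm$rmse))
})

setMethod("show", "PCAModel", function(object) {
    evr <- object@explainedVarianceRatio
    cat("PCAModel:", ncol(object@loadings), "components\n")
    cat("  explained variance (%):",
        paste(sprintf("%.2f", 100 * evr), collapse = ", "), "\n")
})

setMethod("show", "TCATransform", function(object) {
    cat("TCATransform: d =", nrow(object@projection), "-> m =", object@m,
        ", mu =", object@mu, "\n")
    cat(sprintf("  MMD^2: %.4g (input) -> %.4g (subspace); PCA baseline %.4g\n",
                object@mmdBefore, object@mmdAfter, object@mmdPCABaseline))
})

setMethod("show", "CoralTransform", function(object) {
    cat("CoralTransform: d =", nrow(object@recolor),
        ", mean mode:", object@meanMode, "\n")
    cat("  lambda:", paste(sprintf("%.3g", object@lambda), collapse = ", "),
        "\n")
})

setMethod("show", "TransferResult", function(object) {
    t <- object@task
    cat(sprintf("TransferResult: %s -> %s [%s]", t$source, t$target,
                t$method))
    if (!is.null(t$updatingFraction) && t$updatingFraction > 0)
        cat(sprintf(" (updating %.0f%%)", 100 * t$updatingFraction))
    cat("\n")
    cat(sprintf("  R_c = %.4f, RMSEC = %.2f%% | R_p = %.4f, RMSEP = %.2f%%, MAE = %.2f%%\n",
                object@calibration$pearsonR, object@calibration$rmse,
                object@prediction$pearsonR, object@prediction$rmse,
                object@prediction$mae))
    cat("  n_latent =", object@chosenNLatent, ", n_source =",
        object@nSource, ", n_target =", object@nTargetPredicted, "\n")
})

setMethod("show", "StudyReport", function(object) {
    cat("StudyReport: ", nrow(object@tasks), " base tasks, ",
        nrow(object@sweeps), " sweep entries (seed ", object@seed, ")\n",
        sep = "")
    if (length(object@pooled))
        cat(sprintf("  pooled model: R_p = %.4f, RMSEP = %.2f%%\n",
                    object@pooled$prediction$pearsonR,
                    object@pooled$prediction$rmse))
})
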