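#' Serialize and reload study reports
#'
#' `reportToJSON()` renders a [StudyReport-class] as a canonical JSON
#' string at full double precision, so that serialising, parsing and
#' re-serialising is lossless and a rerun with the same master seed
#' produces a byte-identical document.  `studyReportFromJSON()` inverts
#' it.  `writeStudyReport()` writes the JSON document plus two CSV tables
#' (`tasks.csv`, `sweeps.csv`) in the study's standard column layout
#' (`R_c, RMSEC, R_p, RMSEP, MAE`); `readStudyReport()` reloads the JSON.
#'
#' @param report a [StudyReport-class].
#' @param txt a JSON string produced by `reportToJSON()`.
#' @param dir output directory (created if needed).
#' @param path path to a `report.json` file.
#' @return `reportToJSON()`: a JSON character scalar;
#'   `studyReportFromJSON()`, `readStudyReport()`: a
#'   [StudyReport-class]; `writeStudyReport()`: invisibly, `dir`.
#' @name report-io
NULL

#' @rdname report-io
#' @export
reportToJSON <- function(report) {
    stopifnot(is(report, "StudyReport"))
    obj <- list(pooled = report@pooled,
                tasks = report@tasks,
                sweeps = report@sweeps,
                config = report@config,
                seed = report@seed)
    as.character(jsonlite::toJSON(obj, dataframe = "columns",
                                  auto_unbox = TRUE, digits = I(17),
                                  null = "null", pretty = TRUE))
}

#' @rdname report-io
#' @export
studyReportFromJSON <- function(txt) {
    obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
    tasks <- as.data.frame(obj$tasks, stringsAsFactors = FALSE)
    sweeps <- as.data.frame(obj$sweeps, stringsAsFactors = FALSE)
    fixTypes <- function(df) {
        if (!nrow(df)) return(df)
        for (nm in c("n_latent", "n_source", "n_target"))
            df[[nm]] <- as.integer(df[[nm]])
        for (nm in c("fraction", "R_c", "RMSEC", "R_p", "RMSEP", "MAE"))
            df[[nm]] <- as.numeric(df[[nm]])
        df
    }
    tasks <- fixTypes(tasks)
    sweeps <- fixTypes(sweeps)
    pooled <- obj$pooled
    for (nm in c("nCalibration", "nPrediction", "nTotal", "nLatent"))
        pooled[[nm]] <- as.integer(pooled[[nm]])
    new("StudyReport", pooled = pooled, tasks = tasks, sweeps = sweeps,
        config = obj$config, seed = as.integer(obj$seed))
}

#' @rdname report-io
#' @export
writeStudyReport <- function(report, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(reportToJSON(report), file.path(dir, "report.json"))
    data.table::fwrite(report@tasks, file.path(dir, "tasks.csv"))
    data.table::fwrite(report@sweeps, file.path(dir, "sweeps.csv"))
    invisible(dir)
}

#' @rdname report-io
#' @export
readStudyReport <- function(path) {
    if (dir.exists(path)) path <- file.path(path, "report.json")
    studyReportFromJSON(paste(readLines(path), collapse = "\n"))
}

#' Export or import a fitted model or transform as JSON
#'
#' Writes the numeric content of a [PLSRModel-class], [TCATransform-class]
#' or [CoralTransform-class] (means, coefficient/projection matrices,
#' hyperparameters, diagnostics) together with a grid fingerprint, so a
#' fit can be reused by the command-line tools without refitting.
#'
#' @param object a supported model/transform object.
#' @param path destination (`exportModel`) or source (`importModel`) file.
#' @return `importModel()` returns the reconstructed object;
#'   `exportModel()` invisibly returns `path`.
#' @export
exportModel <- function(object, path) {
    cls <- class(object)[1L]
    slots <- slotNames(object)
    payload <- stats::setNames(lapply(slots, function(s) slot(object, s)),
                               slots)
    obj <- list(class = cls, payload = payload)
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = I(17), null = "null")),
               path)
    invisible(path)
}

#' @rdname exportModel
#' @export
importModel <- function(path) {
    obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                              simplifyVector = TRUE)
    cls <- obj$class
    if (!cls %in% c("PLSRModel", "TCATransform", "CoralTransform"))
        stop("unsupported model class: ", cls)
    p <- obj$payload
    toMatrix <- function(x) if (is.matrix(x)) x else as.matrix(x)
    switch(cls,
        PLSRModel = new("PLSRModel", xMean = p$xMean, yMean = p$yMean,
                        nLatent = as.integer(p$nLatent),
                        coefficients = p$coefficients,
                        coefficientPath = toMatrix(p$coefficientPath),
                        trainingMetrics = p$trainingMetrics),
        TCATransform = new("TCATransform",
                           projection = toMatrix(p$projection),
                           combinedMean = p$combinedMean, mu = p$mu,
                           m = as.integer(p$m), mmdBefore = p$mmdBefore,
                           mmdAfter = p$mmdAfter,
                           mmdPCABaseline = p$mmdPCABaseline),
        CoralTransform = new("CoralTransform", sourceMean = p$sourceMean,
                             targetMean = p$targetMean,
                             recolor = toMatrix(p$recolor),
                             lambda = stats::setNames(as.numeric(p$lambda),
                                                      names(p$lambda)),
                             meanMode = p$meanMode))
}
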