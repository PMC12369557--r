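#' Configuration for transfer experiments
#'
#' Collects the model and study hyperparameters with their defaults: PLSR
#' latent-variable selection (`maxLV`, `kFolds`), the TCA subspace
#' (`m`, `mu`), CORAL shrinkage and mean handling (`lambda`,
#' `coralMeanMode`), the updating fractions, which pairs/methods get an
#' updating sweep, the updating sample-selection mode, and the master
#' seed.
#'
#' @param maxLV cap on latent variables considered by cross-validation
#'   (further capped at `min(n - 1, d)` per fit); default 20.
#' @param kFolds cross-validation folds; default 10.
#' @param m TCA subspace dimension; default 30 (capped at
#'   `min(d, n_s + n_t)`).
#' @param mu TCA ridge; default 0.003.
#' @param lambda CORAL shrinkage; `NULL` = relative default (see
#'   [coralFit()]).
#' @param coralMeanMode `"match"` or `"none"`.
#' @param fractions updating fractions for sweeps; default 1%-10%.
#' @param sweepPairs list of `c(source, target)` label pairs to sweep in
#'   [runFullStudy()]; `NULL` = none.
#' @param sweepMethods methods swept for each sweep pair.
#' @param updateSelection `"systematic"` (even coverage of the y-sorted
#'   target) or `"random"`.
#' @param seed master seed; per-task seeds are derived from it
#'   deterministically.
#' @return a named list of class `"transferConfig"`.
#' @export
transferConfig <- function(maxLV = 20L, kFolds = 10L, m = 30L, mu = 0.003,
                           lambda = NULL, coralMeanMode = "match",
                           fractions = seq(0.01, 0.10, by = 0.01),
                           sweepPairs = NULL,
                           sweepMethods = c("direct", "tca"),
                           updateSelection = "systematic", seed = 1L) {
    cfg <- list(maxLV = as.integer(maxLV), kFolds = as.integer(kFolds),
                m = as.integer(m), mu = mu, lambda = lambda,
                coralMeanMode = match.arg(coralMeanMode,
                                          c("match", "none")),
                fractions = fractions, sweepPairs = sweepPairs,
                sweepMethods = sweepMethods,
                updateSelection = match.arg(updateSelection,
                                            c("systematic", "random")),
                seed = as.integer(seed))
    class(cfg) <- "transferConfig"
    cfg
}

checkGrids <- function(source, target) {
    ws <- wavenumbers(source); wt <- wavenumbers(target)
    if (length(ws) != length(wt) || any(ws != wt))
        stop("validation error: source and target wavenumber grids differ")
}

#' Pooled-brands calibration experiment
#'
#' Merges all brand datasets, splits with the sorted interleaved 2:1 rule
#' on the merged targets, selects the latent-variable count by k-fold
#' cross-validation on the calibration set, fits PLSR and evaluates on the
#' prediction set.
#'
#' @param datasets named list of [SpectralSet-class] objects on a common
#'   grid.
#' @param config a [transferConfig()].
#' @return list with `calibration` (R_c, RMSEC), `prediction` (R_p, RMSEP,
#'   MAE), `nCalibration`, `nPrediction`, `nTotal` and `nLatent`.
#' @export
pooledModelExperiment <- function(datasets, config = transferConfig()) {
    stopifnot(length(datasets) >= 1L)
    for (d in datasets[-1L]) checkGrids(datasets[[1L]], d)
    merged <- do.call(BiocGenerics::cbind, unname(datasets))
    y <- blendTarget(merged)
    if (length(y) < 3L) stop("merged dataset has fewer than 3 samples")
    X <- featureMatrix(merged)
    sp <- sortedInterleavedSplit(y)
    Xc <- X[sp$calibration, , drop = FALSE]; yc <- y[sp$calibration]
    sel <- selectLatentVariables(Xc, yc, maxLV = config$maxLV,
                                 kFolds = config$kFolds,
                                 seed = childSeed(config$seed, 991L))
    fit <- plsrFit(Xc, yc, sel$nLatent)
    pm <- computeMetrics(y[sp$prediction],
                         plsrPredict(fit, X[sp$prediction, , drop = FALSE]))
    list(calibration = fit@trainingMetrics,
         prediction = pm,
         nCalibration = length(sp$calibration),
         nPrediction = length(sp$prediction),
         nTotal = length(y), nLatent = fit@nLatent)
}

#' Run one cross-brand transfer task
#'
#' Calibrates on the source brand and predicts the target brand with one
#' of three methods: `"direct"` (PLSR on raw source spectra), `"tca"`
#' (fit a transfer-component projection on both domains' spectra, project
#' both, calibrate on projected source, predict projected target) or
#' `"coral"` (recolor the source toward the target covariance, calibrate
#' on the transformed source, predict the raw target).  The
#' latent-variable count is re-selected by cross-validation inside the
#' task on the (possibly transformed) calibration features; calibration
#' metrics are reported in the space the model was fitted in.
#'
#' @param source,target [SpectralSet-class] datasets on a common grid.
#' @param method one of `"direct"`, `"tca"`, `"coral"`.
#' @param config a [transferConfig()].
#' @param updatingFraction recorded in the result's task description (the
#'   updating itself is done by [updateDomains()] beforehand).
#' @return a [TransferResult-class].
#' @export
runTransferTask <- function(source, target,
                            method = c("direct", "tca", "coral"),
                            config = transferConfig(),
                            updatingFraction = 0) {
    method <- match.arg(method)
    checkGrids(source, target)
    Xs <- featureMatrix(source); ys <- blendTarget(source)
    Xt <- featureMatrix(target); yt <- blendTarget(target)
    if (method == "tca") {
        mEff <- min(config$m, ncol(Xs), nrow(Xs) + nrow(Xt))
        tf <- tcaFit(Xs, Xt, m = mEff, mu = config$mu)
        Fs <- tcaTransform(tf, Xs); Ft <- tcaTransform(tf, Xt)
    } else if (method == "coral") {
        tf <- coralFit(Xs, Xt, lambda = config$lambda,
                       meanMode = config$coralMeanMode)
        Fs <- coralTransform(tf, Xs); Ft <- Xt
    } else {
        Fs <- Xs; Ft <- Xt
    }
    sel <- selectLatentVariables(Fs, ys, maxLV = config$maxLV,
                                 kFolds = config$kFolds,
                                 seed = childSeed(config$seed, 17L))
    fit <- plsrFit(Fs, ys, sel$nLatent)
    pm <- computeMetrics(yt, plsrPredict(fit, Ft))
    srcBrand <- unique(brands(source))
    new("TransferResult",
        task = list(source = paste(srcBrand, collapse = "+"),
                    target = paste(unique(brands(target)), collapse = "+"),
                    method = method, updatingFraction = updatingFraction,
                    hyperparameters = list(maxLV = config$maxLV,
                                           kFolds = config$kFolds,
                                           m = config$m, mu = config$mu,
                                           lambda = config$lambda,
                                           coralMeanMode = config$coralMeanMode,
                                           seed = config$seed)),
        calibration = fit@trainingMetrics, prediction = pm,
        nSource = ncol(source), nTargetPredicted = ncol(target),
        chosenNLatent = fit@nLatent)
}

#' Move a fraction of target samples into the source domain
#'
#' Model updating: `k = round(fraction * n_target)` target samples are
#' appended to the source (keeping their labels) and removed from the
#' target, so the prediction set stays disjoint from the calibration pool.
#' Selection modes: `"systematic"` takes evenly spaced positions over the
#' y-sorted target (every `n/k`-th sample, covering the target range
#' deterministically); `"random"` takes a seeded uniform draw.
#'
#' @param source,target [SpectralSet-class] datasets.
#' @param fraction proportion of target samples to move, in \[0, 0.5).
#' @param selectionMode `"systematic"` or `"random"`.
#' @param seed RNG seed (used by `"random"` mode).
#' @return list with `source` (updated), `target` (reduced) and `movedIDs`.
#' @export
updateDomains <- function(source, target, fraction,
                          selectionMode = c("systematic", "random"),
                          seed = 1L) {
    selectionMode <- match.arg(selectionMode)
    if (!is.finite(fraction) || fraction < 0 || fraction >= 0.5)
        stop("fraction must lie in [0, 0.5)")
    nt <- ncol(target)
    k <- round(fraction * nt)
    if (k == 0L)
        return(list(source = source, target = target,
                    movedIDs = character()))
    if (nt - k < 3L)
        stop("fraction leaves fewer than 3 target samples")
    idx <- if (selectionMode == "systematic") {
        ord <- order(blendTarget(target))
        ord[round(seq_len(k) * nt / k)]
    } else {
        withSeed(seed, sample(nt, k))
    }
    idx <- sort(idx)
    moved <- target[, idx]
    list(source = BiocGenerics::cbind(source, moved),
         target = target[, -idx],
         movedIDs = sampleIDs(moved))
}

#' Sweep model updating over a list of fractions
#'
#' For each fraction: update the domains, then run the transfer task with
#' the given method on the updated pair.  `method = "direct"` realises
#' Updated-PLSR, `"tca"` Updated-TCA-PLSR and `"coral"`
#' Updated-Coral-PLSR (updating happens before any domain alignment).
#'
#' @param source,target [SpectralSet-class] datasets.
#' @param method transfer method, as in [runTransferTask()].
#' @param fractions numeric vector of updating fractions in (0, 0.5).
#' @param config a [transferConfig()].
#' @return list of [TransferResult-class], one per fraction (named by
#'   fraction).
#' @export
runUpdatedSweep <- function(source, target, method,
                            fractions = seq(0.01, 0.10, by = 0.01),
                            config = transferConfig()) {
    out <- vector("list", length(fractions))
    names(out) <- format(fractions)
    for (i in seq_along(fractions)) {
        up <- updateDomains(source, target, fractions[i],
                            selectionMode = config$updateSelection,
                            seed = childSeed(config$seed, 300L + i))
        out[[i]] <- runTransferTask(up$source, up$target, method, config,
                                    updatingFraction = fractions[i])
    }
    out
}

resultRow <- function(res) {
    data.frame(source = res@task$source, target = res@task$target,
               method = res@task$method,
               fraction = res@task$updatingFraction,
               R_c = res@calibration$pearsonR,
               RMSEC = res@calibration$rmse,
               R_p = res@prediction$pearsonR,
               RMSEP = res@prediction$rmse,
               MAE = res@prediction$mae,
               n_latent = res@chosenNLatent,
               n_source = res@nSource,
               n_target = res@nTargetPredicted,
               stringsAsFactors = FALSE)
}

#' Run the full multi-brand transfer study
#'
#' The pooled-brands experiment, every ordered brand pair under each of
#' the three base methods (4 brands give 12 transfer tasks per method),
#' and updating sweeps for the configured pairs/methods.  A single master
#' seed fans out deterministically to per-task seeds, so the report is
#' bit-reproducible.
#'
#' @param datasets named list of >= 2 [SpectralSet-class] brand datasets
#'   on a common grid; names are the brand labels.
#' @param config a [transferConfig()]; `sweepPairs` selects which ordered
#'   pairs get an updating sweep with `sweepMethods` over `fractions`.
#' @param methods base methods to run for every ordered pair.
#' @return a [StudyReport-class].
#' @export
runFullStudy <- function(datasets, config = transferConfig(),
                         methods = c("direct", "tca", "coral")) {
    stopifnot(length(datasets) >= 2L, !is.null(names(datasets)))
    pooled <- pooledModelExperiment(datasets, config)
    labels <- names(datasets)
    rows <- list()
    taskIdx <- 0L
    for (src in labels) for (tgt in labels) {
        if (src == tgt) next
        taskIdx <- taskIdx + 1L
        for (meth in methods) {
            cfg <- config
            cfg$seed <- childSeed(config$seed, taskIdx)
            rows[[length(rows) + 1L]] <-
                resultRow(runTransferTask(datasets[[src]], datasets[[tgt]],
                                          meth, cfg))
        }
    }
    tasks <- do.call(rbind, rows)
    srows <- list()
    for (p in config$sweepPairs) {
        if (!all(p %in% labels)) next
        for (meth in config$sweepMethods) {
            cfg <- config
            cfg$seed <- childSeed(config$seed,
                                  5000L + match(p[1L], labels) * 10L +
                                      match(p[2L], labels))
            res <- runUpdatedSweep(datasets[[p[1L]]], datasets[[p[2L]]],
                                   meth, config$fractions, cfg)
            srows <- c(srows, lapply(res, resultRow))
        }
    }
    sweeps <- if (length(srows)) do.call(rbind, srows) else
        resultRow(new("TransferResult",
                      task = list(source = "", target = "", method = "",
                                  updatingFraction = 0),
                      calibration = list(pearsonR = 0, rmse = 0),
                      prediction = list(pearsonR = 0, rmse = 0, mae = 0),
                      nSource = 0L, nTargetPredicted = 0L,
                      chosenNLatent = 0L))[0L, ]
    rownames(tasks) <- NULL; rownames(sweeps) <- NULL
    cfgOut <- unclass(config)
    cfgOut$lambda <- if (is.null(cfgOut$lambda)) "relative-default"
                     else cfgOut$lambda
    cfgOut$sweepPairs <- lapply(config$sweepPairs, as.character)
    new("StudyReport", pooled = pooled, tasks = tasks, sweeps = sweeps,
        config = cfgOut, seed = config$seed)
}
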