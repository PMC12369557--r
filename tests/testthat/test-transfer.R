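# A compact two-brand world for orchestration tests.
makePair <- function(noiseSD = 0.005, seed = 1, grid = coarseGrid()) {
    lib <- makeComponentLibrary(grid, seed = 1, silkVariants = "V")
    src <- synthesizeDataset(lib,
        brandDesign("S", 60, list(tobacco_silk = c(60, 100),
                                  cut_stem = c(0, 40))),
        domainShift(noiseSD = noiseSD), seed = seed)
    tgt <- synthesizeDataset(lib,
        brandDesign("T", 50, list(tobacco_silk = c(70, 100),
                                  fermented_cut_stem = c(0, 30)),
                    silkVariant = "V"),
        domainShift(offset = 0.01, noiseSD = noiseSD), seed = seed + 1)
    list(src = src, tgt = tgt)
}

test_that("self-transfer is an identity check for every method", {
    p <- makePair()
    cfg <- transferConfig(seed = 2, kFolds = 5, maxLV = 8, m = 10)
    rd <- runTransferTask(p$src, p$src, "direct", cfg)
    expect_equal(rd@prediction$rmse, rd@calibration$rmse, tolerance = 1e-12)
    for (meth in c("tca", "coral")) {
        r <- runTransferTask(p$src, p$src, meth, cfg)
        expect_lte(r@prediction$rmse, r@calibration$rmse + 1e-6)
    }
})

test_that("TCA on identical zero-noise domains matches direct transfer", {
    # noiseless data have mixture-limited rank, so a 10-D subspace is
    # lossless and the projected model reproduces the raw-spectra one
    p <- makePair(noiseSD = 0)
    cfg <- transferConfig(seed = 3, kFolds = 5, maxLV = 6, m = 10)
    a <- runTransferTask(p$src, p$src, "direct", cfg)
    b <- runTransferTask(p$src, p$src, "tca", cfg)
    expect_equal(b@prediction$rmse, a@prediction$rmse, tolerance = 1e-6)
    expect_equal(b@prediction$mae, a@prediction$mae, tolerance = 1e-6)
})

test_that("updating moves the requested samples without leakage", {
    p <- makePair()
    up0 <- updateDomains(p$src, p$tgt, 0)
    expect_identical(sampleIDs(up0$source), sampleIDs(p$src))
    expect_identical(sampleIDs(up0$target), sampleIDs(p$tgt))

    up <- updateDomains(p$src, p$tgt, 0.10)
    expect_identical(ncol(up$source), 65L)
    expect_identical(ncol(up$target), 45L)
    expect_length(up$movedIDs, 5L)
    expect_length(intersect(up$movedIDs, sampleIDs(up$target)), 0L)
    expect_true(all(up$movedIDs %in% sampleIDs(p$tgt)))
    # conservation at every fraction, both selection modes
    for (f in c(0.02, 0.05, 0.1, 0.25)) for (mode in c("systematic", "random")) {
        u <- updateDomains(p$src, p$tgt, f, selectionMode = mode, seed = 4)
        expect_identical(ncol(u$source) + ncol(u$target),
                         ncol(p$src) + ncol(p$tgt))
        expect_length(intersect(sampleIDs(u$source), sampleIDs(u$target)), 0L)
    }
    # systematic selection covers the target response range
    u <- updateDomains(p$src, p$tgt, 0.1, selectionMode = "systematic")
    yMoved <- blendTarget(p$tgt)[match(u$movedIDs, sampleIDs(p$tgt))]
    expect_gt(diff(range(yMoved)), 0.6 * diff(range(blendTarget(p$tgt))))
    expect_error(updateDomains(p$src, p$tgt, 0.5), "fraction")
    expect_error(updateDomains(p$src, p$tgt[, 1:4], 0.49),
                 "fewer than 3")
})

test_that("a sweep is the composition of updating and a transfer task", {
    p <- makePair()
    cfg <- transferConfig(seed = 5, kFolds = 5, maxLV = 6, m = 10)
    sw <- runUpdatedSweep(p$src, p$tgt, "direct", fractions = 0.05, cfg)
    expect_length(sw, 1L)
    up <- updateDomains(p$src, p$tgt, 0.05,
                        selectionMode = cfg$updateSelection,
                        seed = nirtransfer:::childSeed(cfg$seed, 301L))
    manual <- runTransferTask(up$source, up$target, "direct", cfg,
                              updatingFraction = 0.05)
    expect_equal(sw[[1]]@prediction, manual@prediction)
    expect_equal(sw[[1]]@calibration, manual@calibration)
    expect_identical(sw[[1]]@nSource, 62L)      # 60 + round(0.05 * 50)
    expect_identical(sw[[1]]@nTargetPredicted, 48L)
})

test_that("the full study enumerates tasks, round-trips and is deterministic", {
    p <- makePair(grid = coarseGrid(100))
    datasets <- list(S = p$src, T = p$tgt)
    cfg <- transferConfig(seed = 6, kFolds = 5, maxLV = 5, m = 8,
                          fractions = c(0.05, 0.10),
                          sweepPairs = list(c("S", "T")),
                          sweepMethods = "direct")
    rep1 <- runFullStudy(datasets, cfg)
    expect_identical(nrow(rep1@tasks), 6L)   # 2 ordered pairs x 3 methods
    expect_identical(nrow(rep1@sweeps), 2L)
    expect_true(all(is.finite(rep1@tasks$RMSEP)))
    # lossless serialisation
    txt <- reportToJSON(rep1)
    back <- studyReportFromJSON(txt)
    expect_identical(back@tasks, rep1@tasks)
    expect_identical(back@sweeps, rep1@sweeps)
    expect_identical(back@pooled, rep1@pooled)
    expect_identical(reportToJSON(back), txt)
    # byte-identical rerun under the same master seed
    rep2 <- runFullStudy(datasets, cfg)
    expect_identical(reportToJSON(rep2), txt)
    # file round trip
    dir <- withr::local_tempdir()
    writeStudyReport(rep1, dir)
    expect_identical(reportToJSON(readStudyReport(dir)), txt)
})

test_that("fitted models and transforms survive JSON export", {
    p <- makePair()
    Xs <- absorbance(p$src); Xt <- absorbance(p$tgt)
    fit <- plsrFit(Xs, blendTarget(p$src), 4)
    tf <- tcaFit(Xs, Xt, m = 6)
    cf <- coralFit(Xs, Xt)
    dir <- withr::local_tempdir()
    for (obj in list(fit, tf, cf)) {
        path <- file.path(dir, paste0(class(obj), ".json"))
        exportModel(obj, path)
        back <- importModel(path)
        expect_s4_class(back, class(obj))
    }
    fit2 <- importModel(file.path(dir, "PLSRModel.json"))
    expect_equal(plsrPredict(fit2, Xt), plsrPredict(fit, Xt))
    tf2 <- importModel(file.path(dir, "TCATransform.json"))
    expect_equal(tcaTransform(tf2, Xt), tcaTransform(tf, Xt))
    cf2 <- importModel(file.path(dir, "CoralTransform.json"))
    expect_equal(coralTransform(cf2, Xs), coralTransform(cf, Xs))
})
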