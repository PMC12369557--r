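test_that("pcaFit matches the singular-value oracle and handles rank deficiency", {
    set.seed(11)
    X <- matrix(rnorm(20 * 50), 20, 50)
    k <- 19L
    m <- pcaFit(X, k)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(Xc), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(m@explainedVarianceRatio, (ev / sum(ev))[seq_len(k)],
                 tolerance = 1e-10)
    expect_equal(sum(m@explainedVarianceRatio), 1, tolerance = 1e-10)
    expect_equal(crossprod(m@loadings), diag(k), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(k))
        expect_gt(m@loadings[which.max(abs(m@loadings[, j])), j], 0)

    # data on a 2-D affine plane: third component explains nothing
    B <- matrix(rnorm(2 * 10), 2, 10)
    plane <- matrix(rnorm(30 * 2), 30, 2) %*% B
    p <- pcaFit(plane, 3)
    expect_lt(p@explainedVarianceRatio[3], 1e-12)
    expect_error(pcaFit(X, 25), "min")
})

test_that("plsrFit with full rank equals ordinary least squares", {
    set.seed(21)
    for (rep in 1:5) {
        X <- matrix(rnorm(60 * 10), 60, 10)
        y <- rnorm(60)
        Xnew <- matrix(rnorm(20 * 10), 20, 10)
        fit <- plsrFit(X, y, 10)
        expect_equal(plsrPredict(fit, Xnew), olsPredict(X, y, Xnew),
                     tolerance = 1e-8)
    }
})

test_that("plsrFit recovers noiseless linear relations", {
    set.seed(31)
    S <- matrix(rnorm(40 * 3), 40, 3)           # 3 latent factors
    L <- matrix(rnorm(3 * 25), 3, 25)
    X <- S %*% L
    y <- 2 + drop(S %*% c(1, -2, 0.5))
    fit <- plsrFit(X, y, 3)
    expect_lt(fit@trainingMetrics$rmse, 1e-8)
    # prediction on new samples from the same model is exact
    S2 <- matrix(rnorm(10 * 3), 10, 3)
    expect_equal(plsrPredict(fit, S2 %*% L), 2 + drop(S2 %*% c(1, -2, 0.5)),
                 tolerance = 1e-8)
})

test_that("plsr coefficients follow structure and centering identities", {
    set.seed(41)
    # single varying column -> coefficient support on that column only
    X <- matrix(5, 30, 4)
    X[, 3] <- rnorm(30)
    y <- 1 + 2 * X[, 3]
    fit <- plsrFit(X, y, 1)
    expect_equal(fit@coefficients[c(1, 2, 4)], rep(0, 3), tolerance = 1e-10)
    expect_gt(abs(fit@coefficients[3]), 0)
    # predicting the model's own mean row returns yMean
    expect_equal(plsrPredict(fit, matrix(fit@xMean, 1)), fit@yMean)
    # extrapolation is not clipped and follows the affine formula
    far <- matrix(fit@xMean, 1) + c(0, 0, 1e4, 0)
    expect_equal(plsrPredict(fit, far),
                 fit@yMean + 1e4 * fit@coefficients[3])
})

test_that("SIMPLS is nested and agrees with NIPALS on univariate y", {
    set.seed(51)
    X <- matrix(rnorm(35 * 12), 35, 12)
    y <- drop(X %*% rnorm(12)) + rnorm(35, sd = 0.3)
    big <- plsrFit(X, y, 6)
    for (a in c(1L, 3L, 5L)) {
        small <- plsrFit(X, y, a)
        expect_equal(small@coefficients, big@coefficientPath[, a],
                     tolerance = 1e-10)
        expect_equal(plsrPredict(big, X, nLatent = a), plsrPredict(small, X),
                     tolerance = 1e-10)
        nip <- nipalsCoefficients(X, y, a)
        expect_equal(small@coefficients, nip$B, tolerance = 1e-8)
    }
    expect_error(plsrFit(X, rep(2, 35), 2), "constant")
})

test_that("cross-validated latent-variable selection is parsimonious,
           reproducible and finds the true factor count", {
    set.seed(61)
    # exactly one latent direction: ties break to 1
    t1 <- rnorm(40)
    X1 <- outer(t1, rnorm(15))
    sel1 <- selectLatentVariables(X1, 3 + 2 * t1, maxLV = 5, kFolds = 5,
                                  seed = 9)
    expect_identical(sel1$nLatent, 1L)
    # reproducible per seed
    X <- matrix(rnorm(80 * 30), 80, 30)
    y <- drop(X %*% rnorm(30)) + rnorm(80)
    a <- selectLatentVariables(X, y, maxLV = 10, kFolds = 10, seed = 5)
    b <- selectLatentVariables(X, y, maxLV = 10, kFolds = 10, seed = 5)
    expect_identical(a, b)
    # 4 independent spectral factors driving y: recovered within +/- 1,
    # cross-checked against an independent fold-by-fold CV sweep
    set.seed(71)
    S <- matrix(rnorm(90 * 4), 90, 4)
    L <- matrix(rnorm(4 * 40), 4, 40)
    X4 <- S %*% L + matrix(rnorm(90 * 40, sd = 0.05), 90, 40)
    y4 <- drop(S %*% c(2, -1, 1.5, 0.8)) + rnorm(90, sd = 0.05)
    sel4 <- selectLatentVariables(X4, y4, maxLV = 10, kFolds = 10, seed = 3)
    expect_true(abs(sel4$nLatent - 4L) <= 1L)
    fold <- local({set.seed(3); sample(rep(1:10, length.out = 90))})
    sse <- numeric(10)
    for (f in 1:10) for (a in 1:10) {
        m <- plsrFit(X4[fold != f, ], y4[fold != f], a)
        sse[a] <- sse[a] + sum((y4[fold == f] -
                                plsrPredict(m, X4[fold == f, ]))^2)
    }
    expect_identical(sel4$nLatent, as.integer(which.min(sse)))
    expect_error(selectLatentVariables(X4, y4, kFolds = 95), "exceeds")
})

test_that("the sorted interleaved split follows the triple rule", {
    sp <- sortedInterleavedSplit(seq(10, 90, by = 10))
    expect_identical(sp$calibration, c(1L, 3L, 4L, 6L, 7L, 9L))
    expect_identical(sp$prediction, c(2L, 5L, 8L))
    # 2:1 exactly when n is a multiple of three; remainder to calibration
    y <- runif(300)
    sp2 <- sortedInterleavedSplit(y)
    expect_identical(length(sp2$calibration), 200L)
    expect_identical(length(sp2$prediction), 100L)
    sp3 <- sortedInterleavedSplit(runif(301))
    expect_identical(length(sp3$prediction), 100L)
    # permutation invariance for unique y: same samples selected
    set.seed(81)
    yy <- sample(seq_len(50))
    perm <- sample(50)
    a <- sortedInterleavedSplit(yy)
    b <- sortedInterleavedSplit(yy[perm])
    expect_setequal(yy[a$prediction], yy[perm][b$prediction])
    expect_error(sortedInterleavedSplit(c(1, 2)), "at least 3")
})

test_that("metrics match hand-computed values and scale correctly", {
    m <- computeMetrics(c(1, 2, 3), c(1, 2, 5))
    expect_equal(m$mae, 2 / 3)
    expect_equal(m$rmse, sqrt(4 / 3))
    z <- computeMetrics(1:5, 1:5)
    expect_identical(c(z$rmse, z$mae), c(0, 0))
    sh <- computeMetrics(c(1, 2, 4), c(1, 2, 4) + 5)
    expect_equal(sh$pearsonR, 1)
    expect_equal(sh$rmse, 5)
    expect_error(computeMetrics(c(1, 2, 3), rep(1, 3)), "zero-variance")
    # rmse >= mae always; both scale linearly with residual scale
    set.seed(91)
    for (i in 1:20) {
        yt <- rnorm(15); yp <- rnorm(15)
        mm <- computeMetrics(yt, yp)
        expect_gte(mm$rmse, mm$mae)
        m2 <- computeMetrics(3 * yt, 3 * yp)
        expect_equal(m2$rmse, 3 * mm$rmse)
        expect_equal(m2$mae, 3 * mm$mae)
    }
})
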