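test_that("linear-kernel MMD matches hand values and is translation invariant", {
    A <- matrix(0, 4, 2)
    B <- matrix(rep(c(3, 4), each = 4), 4, 2)
    expect_identical(mmdLinear(A, A), 0)
    expect_equal(mmdLinear(A, B), 25)
    set.seed(1)
    X <- matrix(rnorm(20), 10, 2); Y <- matrix(rnorm(16), 8, 2)
    v <- c(7, -3)
    expect_equal(mmdLinear(X, Y),
                 mmdLinear(sweep(X, 2, v, `+`), sweep(Y, 2, v, `+`)))
    expect_error(mmdLinear(matrix(numeric(0), 0, 2), Y), "empty")
    expect_error(mmdLinear(X, matrix(0, 3, 3)), "dimensions differ")
})

test_that("TCA aligns identical domains perfectly and beats the PCA baseline
           on a shifted pair", {
    set.seed(5)
    X <- matrix(rnorm(40 * 6), 40, 6)
    tf <- tcaFit(X, X, m = 3)
    expect_lte(tf@mmdAfter, 1e-9)
    # two clouds offset along axis 1, informative variance along axis 2
    set.seed(6)
    Xs <- cbind(rnorm(60, 0, 0.1), rnorm(60, 0, 1))
    Xt <- cbind(rnorm(60, 5, 0.1), rnorm(60, 0, 1))
    t1 <- tcaFit(Xs, Xt, m = 1)
    # brute-force both 1-D projections
    Z <- rbind(Xs, Xt); Zc <- scale(Z, center = TRUE, scale = FALSE)
    vPCA <- svd(Zc, nu = 0, nv = 1)$v
    base <- mmdLinear(scale(Xs, center = colMeans(Z), scale = FALSE) %*% vPCA,
                      scale(Xt, center = colMeans(Z), scale = FALSE) %*% vPCA)
    expect_equal(t1@mmdPCABaseline, base, tolerance = 1e-10)
    expect_lt(t1@mmdAfter, t1@mmdPCABaseline)
    expect_lt(t1@mmdAfter, t1@mmdBefore)
    expect_error(tcaFit(Xs, Xt, m = 3), "min")
    expect_error(tcaFit(Xs, Xt, m = 1, mu = 0), "mu")
})

test_that("TCA is deterministic, row-order invariant, and its diagnostics
           are reproducible from the transform", {
    set.seed(7)
    Xs <- matrix(rnorm(30 * 8), 30, 8)
    Xt <- sweep(matrix(rnorm(25 * 8), 25, 8), 2, runif(8), `+`)
    tf <- tcaFit(Xs, Xt, m = 4)
    perm <- sample(30); permT <- sample(25)
    tf2 <- tcaFit(Xs[perm, ], Xt[permT, ], m = 4)
    expect_equal(tf@projection, tf2@projection, tolerance = 1e-8)
    expect_equal(tf@mmdAfter, tf2@mmdAfter, tolerance = 1e-10)
    expect_equal(mmdLinear(tcaTransform(tf, Xs), tcaTransform(tf, Xt)),
                 tf@mmdAfter, tolerance = 1e-12)
    # the combined mean projects to the origin
    expect_equal(drop(tcaTransform(tf, matrix(tf@combinedMean, 1))),
                 rep(0, 4), tolerance = 1e-12)
    expect_error(tcaTransform(tf, matrix(0, 2, 5)), "shape")
    # m = d on full-rank data: the projection is invertible
    full <- tcaFit(Xs, Xt, m = 8, mu = 1e-10)
    expect_identical(qr(full@projection)$rank, 8L)
})

test_that("CORAL reproduces closed-form recolorings", {
    # equal covariances: identity map
    set.seed(8)
    X <- matrix(rnorm(100 * 3), 100, 3)
    same <- coralFit(X, X)
    expect_equal(same@recolor, diag(3), tolerance = 1e-8)
    # diag(4,1) -> diag(1,4): recolor = diag(1/2, 2)
    Xs <- matrixWithCovariance(50, diag(c(4, 1)), seed = 1)
    Xt <- matrixWithCovariance(50, diag(c(1, 4)), seed = 2)
    cf <- coralFit(Xs, Xt, lambda = 0)
    expect_equal(cf@recolor, diag(c(0.5, 2)), tolerance = 1e-8)
    # shrinkage limit: giant lambda forces the identity
    cl <- coralFit(Xs, Xt, lambda = 1e9)
    expect_equal(cl@recolor, diag(2), tolerance = 1e-6)
    # lambda = 0 with singular source covariance names the eigenvalue
    sing <- cbind(rnorm(20), rnorm(20))
    sing <- cbind(sing, sing[, 1] + sing[, 2])
    expect_error(coralFit(sing, matrix(rnorm(60), 20, 3), lambda = 0),
                 "singular")
})

test_that("CORAL matches target covariance and handles both mean modes", {
    set.seed(9)
    Xs <- matrix(rnorm(500 * 8), 500, 8) %*% matrix(rnorm(64), 8, 8)
    Xt <- sweep(matrix(rnorm(500 * 8), 500, 8) %*% matrix(rnorm(64), 8, 8),
                2, 1:8, `+`)
    cf <- coralFit(Xs, Xt, lambda = 0, meanMode = "match")
    Ys <- coralTransform(cf, Xs)
    Ct <- cov(Xt)
    expect_lt(norm(cov(Ys) - Ct, "F") / norm(Ct, "F"), 1e-6)
    expect_equal(colMeans(Ys), cf@targetMean, tolerance = 1e-10)
    # mode "none" with an identity recolor leaves the input unchanged
    idm <- coralFit(Xs, Xs, meanMode = "none")
    expect_equal(coralTransform(idm, Xs), Xs, tolerance = 1e-7)
    expect_error(coralTransform(cf, matrix(0, 2, 5)), "shape")
})

test_that("adaptation composed with PLSR stays affine in the input spectrum", {
    ds <- smallBlendSet(30, seed = 2, noiseSD = 0.005)
    dt <- smallBlendSet(30, seed = 3, noiseSD = 0.005,
                        shift = domainShift(offset = 0.01, noiseSD = 0.005))
    Xs <- absorbance(ds); Xt <- absorbance(dt)
    ys <- blendTarget(ds)
    for (path in c("tca", "coral")) {
        if (path == "tca") {
            tf <- tcaFit(Xs, Xt, m = 10)
            fs <- function(M) tcaTransform(tf, M)
        } else {
            tf <- coralFit(Xs, Xt)
            fs <- function(M) M   # target passes through raw
        }
        model <- plsrFit(if (path == "tca") fs(Xs) else coralTransform(tf, Xs),
                         ys, 3)
        predictPipeline <- function(M) plsrPredict(model, fs(M))
        a <- Xt[1, , drop = FALSE]; b <- Xt[2, , drop = FALSE]
        expect_equal(predictPipeline((a + b) / 2),
                     (predictPipeline(a) + predictPipeline(b)) / 2,
                     tolerance = 1e-10)
    }
})
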