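# Shared fixtures and independent oracles for the suite.  Everything is
# generated in code; no stored data.

coarseGrid <- function(step = 50) defaultGrid(10000, 4000, step)

# A small two-component blended dataset (deterministic).
smallBlendSet <- function(n = 12, seed = 1, noiseSD = 0,
                          shift = domainShift(noiseSD = noiseSD),
                          grid = coarseGrid()) {
    lib <- makeComponentLibrary(grid, seed = 1)
    des <- brandDesign("B2", n, list(tobacco_silk = c(75, 100),
                                     fermented_cut_stem = c(0, 25)))
    synthesizeDataset(lib, des, shift, seed = seed)
}

# Ordinary least squares predictions (QR), the independent oracle for
# full-rank PLSR equivalence.
olsPredict <- function(Xtrain, ytrain, Xnew) {
    fit <- stats::lm.fit(cbind(1, Xtrain), ytrain)
    drop(cbind(1, Xnew) %*% fit$coefficients)
}

# NIPALS PLS1: the classical iterative algorithm, as an independent
# reference for SIMPLS on a univariate response.
nipalsCoefficients <- function(X, y, A) {
    xm <- colMeans(X); ym <- mean(y)
    E <- sweep(X, 2, xm); f <- y - ym
    d <- ncol(X)
    W <- matrix(0, d, A); P <- matrix(0, d, A); q <- numeric(A)
    for (a in seq_len(A)) {
        w <- crossprod(E, f); w <- w / sqrt(sum(w^2))
        t <- E %*% w; tt <- sum(t^2)
        p <- crossprod(E, t) / tt
        qa <- sum(f * t) / tt
        E <- E - t %*% t(p); f <- f - qa * t
        W[, a] <- w; P[, a] <- p; q[a] <- qa
    }
    B <- W %*% solve(t(P) %*% W, q)
    list(xMean = xm, yMean = ym, B = drop(B))
}

# Construct an n x d matrix whose sample covariance is exactly C (n > d).
matrixWithCovariance <- function(n, C, seed = 1) {
    d <- ncol(C)
    set.seed(seed)
    Z <- matrix(rnorm(n * d), n, d)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Z <- qr.Q(qr(Z))[, seq_len(d)] * sqrt(n - 1)   # cov(Z) = I exactly
    R <- chol(C)
    Z %*% R
}

identityShifts <- function(labels = c("B1", "B2", "B3", "B4"))
    stats::setNames(replicate(length(labels), domainShift(),
                              simplify = FALSE), labels)
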