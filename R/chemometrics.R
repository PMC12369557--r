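#' Mean-centered principal component analysis of spectra
#'
#' Diagnostics for spectral variability: loadings ("principal component
#' coefficient" curves) and per-component explained-variance fractions of
#' the mean-centered absorbance matrix, computed by SVD.  Loading signs are
#' fixed so the largest-magnitude element of each column is positive.
#'
#' @param X numeric matrix, n samples x d features (n >= 2).
#' @param k number of components to keep, `k <= min(n - 1, d)`.
#' @return a [PCAModel-class].
#' @examples
#' m <- pcaFit(matrix(rnorm(200), 20), 3)
#' sum(m@explainedVarianceRatio) <= 1
#' @export
pcaFit <- function(X, k) {
    X <- as.matrix(X)
    n <- nrow(X); d <- ncol(X)
    if (n < 2L) stop("need at least 2 samples")
    k <- stopifnotScalarCount(k, "k")
    if (k > min(n - 1L, d))
        stop("k must be <= min(n - 1, d) = ", min(n - 1L, d))
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    sv <- svd(Xc, nu = 0, nv = k)
    tot <- sum(Xc^2)
    evr <- if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k)
    new("PCAModel", meanSpectrum = mu,
        loadings = fixColumnSigns(sv$v),
        explainedVarianceRatio = evr)
}

# SIMPLS for a univariate response.  Returns the centered means and the
# coefficient path B[, a] for a = 1..A (possibly shorter if the effective
# rank is exhausted first).
simplsPath <- function(X, y, A) {
    n <- nrow(X); d <- ncol(X)
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2L, xm); yc <- y - ym
    s <- crossprod(Xc, yc)
    R <- matrix(0, d, A); V <- matrix(0, d, A); Q <- numeric(A)
    B <- matrix(0, d, A)
    ref <- NA_real_
    used <- 0L
    for (a in seq_len(A)) {
        r <- s
        t <- Xc %*% r
        nt2 <- sum(t^2)
        if (!is.finite(nt2) || nt2 <= 0) break
        if (a == 1L) ref <- nt2
        else if (nt2 <= 1e-24 * ref) break
        nt <- sqrt(nt2)
        t <- t / nt; r <- r / nt
        p <- crossprod(Xc, t)
        q <- sum(yc * t)
        v <- p
        if (a > 1L) {
            Va <- V[, seq_len(a - 1L), drop = FALSE]
            v <- v - Va %*% crossprod(Va, p)
        }
        nv <- sqrt(sum(v^2))
        if (nv <= 1e-12 * sqrt(sum(p^2))) break
        v <- v / nv
        s <- s - v %*% crossprod(v, s)
        R[, a] <- r; V[, a] <- v; Q[a] <- q
        B[, a] <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
        used <- a
    }
    list(xMean = xm, yMean = ym,
         B = B[, seq_len(max(used, 0L)), drop = FALSE], rank = used)
}

#' Fit a partial least squares regression model (SIMPLS)
#'
#' Univariate-response PLSR on mean-centered data (no autoscaling), using
#' the deterministic SIMPLS decomposition.  The coefficient path is nested:
#' the a-component coefficients of a larger fit equal those of a smaller
#' one.
#'
#' @param X numeric matrix, n samples x d features.
#' @param y numeric response of length n with nonzero variance (%).
#' @param nLatent number of latent variables,
#'   `1 <= nLatent <= min(n - 1, d)`.
#' @return a [PLSRModel-class] with calibration metrics (R_c, RMSEC)
#'   computed on `(X, y)`.
#' @seealso [plsrPredict()], [selectLatentVariables()]
#' @export
plsrFit <- function(X, y, nLatent) {
    X <- as.matrix(X)
    n <- nrow(X); d <- ncol(X)
    if (n < 2L) stop("need at least 2 samples")
    if (length(y) != n) stop("length(y) must equal nrow(X)")
    if (!is.finite(var(y)) || var(y) == 0)
        stop("fit error: constant response (covariance undefined)")
    nLatent <- stopifnotScalarCount(nLatent, "nLatent")
    if (nLatent > min(n - 1L, d))
        stop("nLatent must be <= min(n - 1, d) = ", min(n - 1L, d))
    path <- simplsPath(X, y, nLatent)
    if (path$rank < nLatent)
        stop("effective rank of X (", path$rank,
             ") is below the requested nLatent (", nLatent, ")")
    b <- path$B[, nLatent]
    fitted <- path$yMean + drop(sweep(X, 2L, path$xMean) %*% b)
    tm <- computeMetrics(y, fitted)
    new("PLSRModel", xMean = path$xMean, yMean = path$yMean,
        nLatent = nLatent, coefficients = b, coefficientPath = path$B,
        trainingMetrics = list(pearsonR = tm$pearsonR, rmse = tm$rmse))
}

#' Predict blending proportions from spectra
#'
#' Applies the affine PLSR map
#' `yhat = yMean + (x - xMean) %*% coefficients`.  Predictions are not
#' clipped: extrapolated inputs may yield values outside \[0, 100\].
#'
#' @param model a [PLSRModel-class].
#' @param X numeric matrix on the model's feature grid (same d).
#' @param nLatent optionally predict with a truncated number of components
#'   (`<= model@nLatent`); default uses the model's own count.
#' @return numeric vector of predictions (%).
#' @export
plsrPredict <- function(model, X, nLatent = NULL) {
    X <- as.matrix(X)
    if (ncol(X) != length(model@xMean))
        stop("shape error: X has ", ncol(X), " features, model expects ",
             length(model@xMean))
    b <- if (is.null(nLatent)) model@coefficients else {
        nLatent <- stopifnotScalarCount(nLatent, "nLatent")
        if (nLatent > model@nLatent)
            stop("nLatent exceeds the fitted count ", model@nLatent)
        model@coefficientPath[, nLatent]
    }
    model@yMean + drop(sweep(X, 2L, model@xMean) %*% b)
}

#' Select the number of latent variables by k-fold cross-validation
#'
#' Folds are formed by a seeded random shuffle; for each fold one SIMPLS
#' path up to `maxLV` is fitted on the training part and held-out RMSE is
#' accumulated for every component count from the nested path.  The
#' smallest count within a 1e-8 relative tolerance of the minimum mean
#' CV-RMSE is returned (ties break toward parsimony).
#'
#' @param X,y calibration spectra and response.
#' @param maxLV largest count to consider (capped at the fold-wise bound
#'   `min(n_train - 1, d)`).
#' @param kFolds number of folds (>= 2, <= n).
#' @param seed integer RNG seed for the fold assignment.
#' @return list with `nLatent` (chosen count) and `cvRMSE` (mean CV-RMSE
#'   per candidate count).
#' @export
selectLatentVariables <- function(X, y, maxLV = NULL, kFolds = 10L,
                                  seed = 1L) {
    X <- as.matrix(X)
    n <- nrow(X); d <- ncol(X)
    kFolds <- stopifnotScalarCount(kFolds, "kFolds")
    if (kFolds < 2L) stop("kFolds must be >= 2")
    if (kFolds > n) stop("kFolds (", kFolds, ") exceeds n (", n, ")")
    if (is.null(maxLV)) maxLV <- min(20L, n - 1L, d)
    maxLV <- stopifnotScalarCount(maxLV, "maxLV")
    maxLV <- min(maxLV, n - ceiling(n / kFolds) - 1L, d)
    if (maxLV < 1L) stop("too few samples for cross-validation")
    # a fold's training part can support more components than the full
    # matrix; never propose a count the final fit cannot realise
    maxLV <- min(maxLV, max(simplsPath(X, y, maxLV)$rank, 1L))
    fold <- withSeed(seed, sample(rep(seq_len(kFolds), length.out = n)))
    sse <- numeric(maxLV); m <- 0L
    for (f in seq_len(kFolds)) {
        tr <- fold != f
        path <- simplsPath(X[tr, , drop = FALSE], y[tr], maxLV)
        Xo <- sweep(X[!tr, , drop = FALSE], 2L, path$xMean)
        for (a in seq_len(maxLV)) {
            pred <- if (path$rank == 0L) rep(path$yMean, nrow(Xo))
                    else path$yMean + drop(Xo %*% path$B[, min(a, path$rank)])
            sse[a] <- sse[a] + sum((y[!tr] - pred)^2)
        }
        m <- m + sum(!tr)
    }
    cvRMSE <- sqrt(sse / m)
    best <- min(cvRMSE)
    nLatent <- which(cvRMSE <= best + 1e-8 * max(best, 1e-300))[1L]
    list(nLatent = as.integer(nLatent), cvRMSE = cvRMSE)
}

#' Sorted interleaved 2:1 calibration/prediction split
#'
#' Samples are sorted by the response (stable; ties keep original order),
#' grouped into consecutive triples, and within each triple the first and
#' third go to calibration and the second to prediction; a trailing
#' remainder of one or two samples goes to calibration.  With n divisible
#' by 3 this yields an exact 2:1 calibration:prediction ratio.
#'
#' @param y numeric response vector, length >= 3.
#' @return list with integer index vectors `calibration` and `prediction`
#'   (indices into the original order).
#' @examples
#' sortedInterleavedSplit(c(10, 20, 30, 40, 50, 60, 70, 80, 90))
#' @export
sortedInterleavedSplit <- function(y) {
    n <- length(y)
    if (n < 3L) stop("need at least 3 samples to split")
    o <- order(y)              # stable: ties by original index
    pos <- seq_len(n)
    inTriple <- pos %% 3L
    pred <- pos[inTriple == 2L & pos <= 3L * (n %/% 3L)]
    list(calibration = sort(o[setdiff(pos, pred)]),
         prediction = sort(o[pred]))
}

#' Regression evaluation metrics
#'
#' Root mean squared error, mean absolute error and the (signed) sample
#' Pearson correlation between reference and predicted values; these are
#' the calibration (R_c, RMSEC) and prediction (R_p, RMSEP, MAE) metrics
#' of the study when applied to the respective sets.
#'
#' @param yTrue,yPred numeric vectors of equal length (>= 1; >= 2 and with
#'   nonzero variance on both sides for the correlation).
#' @return list with `rmse`, `mae` (% units) and `pearsonR`.
#' @examples
#' computeMetrics(c(1, 2, 3), c(1, 2, 5))  # mae 2/3, rmse sqrt(4/3)
#' @export
computeMetrics <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred))
        stop("yTrue and yPred must have equal length")
    if (!length(yTrue)) stop("empty input")
    e <- yTrue - yPred
    r <- if (length(yTrue) >= 2L) {
        if (sd(yTrue) == 0 || sd(yPred) == 0)
            stop("undefined correlation: zero-variance vector")
        cor(yTrue, yPred)
    } else NA_real_
    list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)), pearsonR = r)
}
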