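#' Linear-kernel maximum mean discrepancy
#'
#' The squared Euclidean distance between the mean rows of two feature
#' matrices — the linear-kernel MMD consistent with primal transfer
#' component analysis.  Translation of both domains by the same vector
#' leaves it unchanged.
#'
#' @param A,B numeric matrices with the same number of columns.
#' @return non-negative squared distance.
#' @examples
#' mmdLinear(matrix(0, 4, 2), matrix(rep(c(3, 4), each = 4), 4))  # 25
#' @export
mmdLinear <- function(A, B) {
    A <- as.matrix(A); B <- as.matrix(B)
    if (!nrow(A) || !nrow(B)) stop("empty matrix")
    if (ncol(A) != ncol(B)) stop("feature dimensions differ")
    sum((colMeans(A) - colMeans(B))^2)
}

# Inverse square root of B = mu*I + delta %*% t(delta), in closed form
# (rank-one eigenstructure: eigenvalue mu + |delta|^2 along delta, mu
# elsewhere).  Returns a function that left-multiplies a d-column matrix.
rankOneInvSqrt <- function(delta, mu) {
    s <- sum(delta^2)
    a <- 1 / sqrt(mu)
    if (s == 0) return(function(M) a * M)
    u <- delta / sqrt(s)
    b <- 1 / sqrt(mu + s) - a
    function(M) a * M + u %*% (b * crossprod(u, M))
}

#' Fit a primal transfer-component projection
#'
#' Linear (no-kernel) TCA on raw features: stack source and target, center
#' by the combined mean, and take as projection the leading m eigenvectors
#' of `(Z' L Z + mu I)^{-1} Z' H Z`, where `Z' H Z` is the scatter of the
#' centered stack (variance to preserve) and `Z' L Z` the rank-one MMD
#' matrix `delta delta'` built from the difference of domain means
#' (distributional distance to penalise).  Solved symmetrically by
#' whitening with the closed-form inverse square root of the rank-one
#' update; eigenvector signs are fixed so results are deterministic and
#' invariant to row order.
#'
#' Diagnostics stored on the object: the linear MMD before projection,
#' after projection, and after projecting onto the top-m PCA axes of the
#' stacked data (the variance-only baseline the TCA objective improves
#' upon).
#'
#' @param Xs,Xt source and target feature matrices (shared d).
#' @param m subspace dimension, `m <= min(d, n_s + n_t)`; default 30.
#' @param mu ridge regulariser (> 0) on the distance term; default 0.003.
#'   Small values suppress the between-domain mean-shift direction almost
#'   completely; larger values leave a residual, shrunken trace of it in
#'   the subspace, which target-domain spiking (model updating) can then
#'   exploit.
#' @return a [TCATransform-class].
#' @seealso [tcaTransform()]
#' @export
tcaFit <- function(Xs, Xt, m = 30L, mu = 0.003) {
    Xs <- as.matrix(Xs); Xt <- as.matrix(Xt)
    if (ncol(Xs) != ncol(Xt)) stop("feature dimensions differ")
    d <- ncol(Xs); ns <- nrow(Xs); nt <- nrow(Xt)
    if (!ns || !nt) stop("empty domain")
    m <- stopifnotScalarCount(m, "m")
    if (m > min(d, ns + nt))
        stop("m must be <= min(d, n_s + n_t) = ", min(d, ns + nt))
    if (!is.finite(mu) || mu <= 0) stop("mu must be > 0")
    Z <- rbind(Xs, Xt)
    cm <- colMeans(Z)
    Zc <- sweep(Z, 2L, cm)
    delta <- colMeans(Xs) - colMeans(Xt)
    Bih <- rankOneInvSqrt(delta, mu)
    S <- crossprod(Zc)
    M <- Bih(t(Bih(S)))          # B^{-1/2} S B^{-1/2}, symmetric
    M <- (M + t(M)) / 2
    eg <- tryCatch(eigen(M, symmetric = TRUE),
                   error = function(e)
                       stop("numerical error in the TCA eigenproblem (",
                            conditionMessage(e),
                            "); consider raising mu"))
    W <- fixColumnSigns(Bih(eg$vectors[, seq_len(m), drop = FALSE]))
    dimnames(W) <- NULL
    Ps <- sweep(Xs, 2L, cm) %*% W
    Pt <- sweep(Xt, 2L, cm) %*% W
    sv <- svd(Zc, nu = 0, nv = m)
    Vp <- sv$v
    baseline <- mmdLinear(sweep(Xs, 2L, cm) %*% Vp,
                          sweep(Xt, 2L, cm) %*% Vp)
    new("TCATransform", projection = W, combinedMean = cm, mu = mu,
        m = m, mmdBefore = mmdLinear(Xs, Xt),
        mmdAfter = mmdLinear(Ps, Pt), mmdPCABaseline = baseline)
}

#' Project features into a fitted transfer-component subspace
#'
#' `(X - combinedMean) %*% W`; the same map applies to source, target and
#' any later batch on the same grid.
#'
#' @param transform a [TCATransform-class].
#' @param X numeric matrix on dimension d.
#' @return n x m matrix of projected features.
#' @export
tcaTransform <- function(transform, X) {
    X <- as.matrix(X)
    if (ncol(X) != length(transform@combinedMean))
        stop("shape error: X has ", ncol(X), " features, transform expects ",
             length(transform@combinedMean))
    sweep(X, 2L, transform@combinedMean) %*% transform@projection
}

# Symmetric matrix power with eigenvalue floor at zero; errors on request
# if the matrix is numerically singular (needed for power < 0).
symmetricPower <- function(C, power, label = "covariance",
                           requirePD = FALSE) {
    eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    if (requirePD && min(eg$values) <= 1e-12 * max(abs(eg$values)))
        stop("singularity error: ", label,
             " is numerically singular (smallest eigenvalue ",
             format(min(eg$values), digits = 4),
             "); use lambda > 0")
    pv <- ifelse(vals > 0, vals^power, 0)
    eg$vectors %*% (pv * t(eg$vectors))
}

#' Fit a correlation-alignment (CORAL) recoloring map
#'
#' Whitens the source covariance and recolors with the target covariance:
#' `A = (C_s + lambda_s I)^{-1/2} (C_t + lambda_t I)^{1/2}` via symmetric
#' eigendecomposition square roots (eigenvalues floored at zero before
#' rooting).  With `lambda = 0` the source covariance must be numerically
#' nonsingular.  Because spectra typically have fewer samples than
#' channels, the default shrinkage is relative:
#' `lambda = 1e-6 * trace(C)/d` per covariance.
#'
#' @param Xs,Xt source and target feature matrices (shared d, >= 2 rows
#'   each).
#' @param lambda diagonal shrinkage (absorbance^2).  `NULL` (default) uses
#'   the relative rule above; a scalar applies to both covariances; a
#'   length-2 vector gives source and target shrinkage separately.
#' @param meanMode `"match"` (default: subtract the source mean, recolor,
#'   add the target mean, so downstream regression sees target-centered
#'   data) or `"none"` (recolor the raw features; classic covariance-only
#'   alignment).
#' @return a [CoralTransform-class].
#' @seealso [coralTransform()]
#' @export
coralFit <- function(Xs, Xt, lambda = NULL, meanMode = c("match", "none")) {
    meanMode <- match.arg(meanMode)
    Xs <- as.matrix(Xs); Xt <- as.matrix(Xt)
    if (ncol(Xs) != ncol(Xt)) stop("feature dimensions differ")
    if (nrow(Xs) < 2L || nrow(Xt) < 2L)
        stop("need at least 2 samples per domain")
    d <- ncol(Xs)
    Cs <- cov(Xs); Ct <- cov(Xt)
    if (is.null(lambda))
        lambda <- 1e-6 * c(sum(diag(Cs)), sum(diag(Ct))) / d
    else {
        if (any(!is.finite(lambda)) || any(lambda < 0))
            stop("lambda must be >= 0")
        lambda <- rep_len(as.numeric(lambda), 2L)
    }
    names(lambda) <- c("source", "target")
    CsL <- Cs + diag(lambda[1L], d)
    CtL <- Ct + diag(lambda[2L], d)
    A <- symmetricPower(CsL, -0.5, label = "source covariance",
                        requirePD = lambda[1L] == 0) %*%
         symmetricPower(CtL, 0.5)
    new("CoralTransform", sourceMean = colMeans(Xs),
        targetMean = colMeans(Xt), recolor = A, lambda = lambda,
        meanMode = meanMode)
}

#' Apply a fitted CORAL map to source-domain features
#'
#' In mean mode `"match"`, `(X - sourceMean) %*% A + targetMean`; in mode
#' `"none"`, `X %*% A`.  Target-domain rows pass through unchanged in the
#' transfer pipeline — the target is its own reference frame.
#'
#' @param transform a [CoralTransform-class].
#' @param X source-domain feature matrix on dimension d.
#' @return aligned n x d matrix.
#' @export
coralTransform <- function(transform, X) {
    X <- as.matrix(X)
    d <- length(transform@sourceMean)
    if (ncol(X) != d)
        stop("shape error: X has ", ncol(X), " features, transform expects ",
             d)
    if (transform@meanMode == "match")
        sweep(sweep(X, 2L, transform@sourceMean) %*% transform@recolor,
              2L, transform@targetMean, `+`)
    else
        X %*% transform@recolor
}
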