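# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic per-task seed derived from a master seed; stays within the
# 32-bit integer range R requires.
childSeed <- function(seed, index) {
    as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %%
               2147483629)
}

# Fix eigen/singular-vector sign ambiguity: make the largest-magnitude
# element of each column positive.
fixColumnSigns <- function(M) {
    for (j in seq_len(ncol(M))) {
        i <- which.max(abs(M[, j]))
        if (M[i, j] < 0) M[, j] <- -M[, j]
    }
    M
}

# n x d feature matrix of a SpectralSet (samples in rows).
featureMatrix <- function(ds) {
    X <- absorbance(ds)
    dimnames(X) <- NULL
    X
}

stopifnotScalarCount <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != as.integer(x))
        stop("'", name, "' must be a single positive integer")
    as.integer(x)
}
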