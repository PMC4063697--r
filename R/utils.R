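## Internal numerical helpers shared across modules.

## Two-sided normal P from z, computed in log space so that P is accurate
## (relative error ~1e-12) far into the tail (|z| ~ 13 gives P ~ 1e-40).
pvalFromZ <- function(z) {
    exp(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2))
}

## Upper-tail chi-square P in log space; accurate down to ~1e-300.
chisqTail <- function(x, df) {
    exp(pchisq(x, df = df, lower.tail = FALSE, log.p = TRUE))
}

## Draw n samples from N(0, S) given a correlation/covariance matrix S.
## Cholesky with a PSD fallback via eigendecomposition (zero-clipped).
rmvn <- function(n, S) {
    p <- ncol(S)
    L <- tryCatch(chol(S), error = function(e) {
        es <- eigen(S, symmetric = TRUE)
        ev <- pmax(es$values, 0)
        t(es$vectors %*% (t(es$vectors) * sqrt(ev)))
    })
    matrix(rnorm(n * p), n, p) %*% L
}

## Validate a correlation matrix: symmetric, unit diagonal, PSD.
checkCorrMatrix <- function(R, name = deparse(substitute(R))) {
    if (!is.matrix(R) || nrow(R) != ncol(R))
        stop(name, " must be a square matrix", call. = FALSE)
    if (max(abs(R - t(R))) > 1e-8)
        stop(name, " must be symmetric", call. = FALSE)
    if (max(abs(diag(R) - 1)) > 1e-8)
        stop(name, " must have unit diagonal", call. = FALSE)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
        stop(name, " must be positive semi-definite", call. = FALSE)
    invisible(TRUE)
}

## Standardize a vector to mean 0, sd 1 (denominator n-1).
zstd <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0)
        stop("cannot standardize a constant vector", call. = FALSE)
    (x - mean(x)) / s
}

## Derive a stream of sub-seeds from one master seed, keeping values well
## inside 32-bit integer range.
deriveSeeds <- function(master, n) {
    (as.integer(master) + 1000003L * seq_len(n)) %% 2147483647L
}
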