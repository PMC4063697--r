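## Independent oracles and small fixture builders shared across tests.

## Exact Hardy-Weinberg tail by direct log-factorial evaluation of the
## conditional genotype distribution (independent of the package's
## recurrence implementation).
hweEnumOracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    na <- 2 * naa + nAa
    R <- min(nA, na)
    if (R == 0) return(1)
    hets <- seq(R %% 2, R, by = 2)
    lp <- vapply(hets, function(h) {
        rh <- (R - h) / 2
        ch <- n - h - rh
        lfactorial(n) - lfactorial(rh) - lfactorial(h) - lfactorial(ch) +
            h * log(2) -
            (lfactorial(2 * n) - lfactorial(nA) - lfactorial(na))
    }, numeric(1))
    pr <- exp(lp)
    pr <- pr / sum(pr)
    pObs <- pr[match(nAa, hets)]
    sum(pr[pr <= pObs * (1 + 1e-12)])
}

## Trivariate-normal log-likelihood for arbitrary mean parameters and a
## Cholesky-parameterized covariance; used by the generic-maximizer oracle.
mvn3LogLik <- function(Y, g, mu, beta, L) {
    S <- crossprod(L)
    R <- Y - rep(1, nrow(Y)) %o% mu - g %o% beta
    ch <- chol(S)
    quad <- sum(backsolve(ch, t(R), transpose = TRUE)^2)
    -0.5 * (nrow(Y) * (3 * log(2 * pi) + 2 * sum(log(diag(ch)))) + quad)
}

## Generic numerical maximizer of the constrained trivariate likelihood
## (all_equal): optimizes mu (3), the shared slope and the upper-triangular
## Cholesky factor (6) with BFGS refined by Nelder-Mead.
mvn3NumericMax <- function(Y, g) {
    n <- nrow(Y)
    start <- c(colMeans(Y), 0, chol(cov(Y) * (n - 1) / n)[upper.tri(
        diag(3), diag = TRUE)])
    unpack <- function(p) {
        L <- matrix(0, 3, 3)
        L[upper.tri(L, diag = TRUE)] <- p[5:10]
        list(mu = p[1:3], beta = rep(p[4], 3), L = L)
    }
    negll <- function(p) {
        u <- unpack(p)
        if (any(abs(diag(u$L)) < 1e-8)) return(1e10)
        -mvn3LogLik(Y, g, u$mu, u$beta, u$L)
    }
    o <- optim(start, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    o <- optim(o$par, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    -o$value
}

## Three-site residual correlation structure used when simulating
## correlated skeletal traits directly (LL, UL, SK order).
siteSigma3 <- function() {
    matrix(c(1, 0.55, 0.20,
             0.55, 1, 0.24,
             0.20, 0.24, 1), 3, 3,
           dimnames = rep(list(c("LL", "UL", "SK")), 2))
}

## Simulate one cohort's (Y, g) for the site-specificity test: traits are
## unit-variance with residual correlation siteSigma3() plus a per-site
## standardized SNP effect.
simSiteCohort <- function(n, beta, p = 0.35) {
    g <- rbinom(n, 2, p)
    gs <- (g - mean(g)) / sd(g)
    Y <- bonesite:::rmvn(n, siteSigma3()) + outer(gs, beta)
    colnames(Y) <- c("LL", "UL", "SK")
    list(Y = Y, g = g)
}

## Small QC-clean panel + phenotypes for module tests.
simSmallCohort <- function(n = 400, m = 800, seed = 1, nCausal = m %/% 2) {
    panel <- simulateGenotypes(cohortSpec("tc", n, m, seed = seed))
    arch <- defaultTraitArchitecture(nCausal = as.integer(nCausal))
    pheno <- simulatePhenotypes(panel, arch, seed = seed + 1000L)
    list(panel = panel, pheno = pheno, arch = arch)
}
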