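#' Compute a genetic relationship matrix
#'
#' GCTA-style estimator: A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i)), with p_i the sample allele frequency of SNP i; the
#' same formula is used on and off the diagonal. Monomorphic SNPs must be
#' removed upstream (QC) and raise an error here.
#'
#' @param panel a \linkS4class{DosagePanel} of QC-passing SNPs (missing
#'   calls are mean-imputed, i.e. contribute zero after centering).
#' @return a \linkS4class{Grm}.
#' @export
computeGrm <- function(panel) {
    stopifnot(methods::is(panel, "DosagePanel"))
    X <- dosages(panel)
    if (anyNA(X)) {
        mu <- rowMeans(X, na.rm = TRUE)
        idx <- which(is.na(X), arr.ind = TRUE)
        X[idx] <- mu[idx[, 1]]
    }
    p <- rowMeans(X) / 2
    if (any(p <= 0 | p >= 1))
        stop("monomorphic SNP in panel; run qcFilter() first")
    W <- (X - 2 * p) / sqrt(2 * p * (1 - p))
    A <- crossprod(W) / nrow(W)
    methods::new("Grm", k = A, ids = colnames(X),
                 mSnps = nrow(X))
}

#' Greedy relatedness pruning
#'
#' Removes individuals until no off-diagonal relationship exceeds the
#' cutoff: repeatedly drop the individual involved in the most
#' above-cutoff pairs (ties broken toward the later id). With the default
#' cutoff 0.025 this removes cryptically related individuals before REML.
#'
#' @param grm a \linkS4class{Grm}.
#' @param cutoff relatedness cutoff (> 0; default 0.025).
#' @return character vector of retained ids.
#' @export
pruneRelated <- function(grm, cutoff = 0.025) {
    if (cutoff <= 0) stop("cutoff must be positive")
    A <- grmMatrix(grm)
    ids <- grmIds(grm)
    alive <- rep(TRUE, length(ids))
    Aoff <- A
    diag(Aoff) <- 0
    repeat {
        over <- (abs(Aoff) > cutoff) & outer(alive, alive, `&`)
        counts <- rowSums(over)
        if (!any(counts > 0)) break
        worst <- which(counts == max(counts))
        alive[worst[length(worst)]] <- FALSE   # tie-break: later id
    }
    ids[alive]
}

grmEigenDecomp <- function(grm, ridge = 1e-6) {
    A <- grmMatrix(grm)
    diag(A) <- diag(A) + ridge
    es <- eigen(A, symmetric = TRUE)
    if (min(es$values) < -1e-8)
        stop("GRM not positive semi-definite after ridge")
    es$values <- pmax(es$values, 0)
    es
}

#' Univariate GREML estimate of SNP-heritability
#'
#' REML for the zero-mean model y ~ N(0, sigma_g^2 A + sigma_e^2 I) on a
#' standardized residual trait. After rotating by the eigenvectors of A the
#' likelihood separates, the total variance profiles out analytically and a
#' 1-D search over the heritability ratio is exact for single-GRM models.
#' The SE comes from the inverse expected information (delta method for the
#' ratio); the test of vg = 0 refers twice the log-likelihood difference to
#' the 50:50 mixture of a point mass at zero and a 1-df chi-square.
#'
#' @param y standardized residual trait (same order as the GRM ids).
#' @param grm a \linkS4class{Grm}, or a precomputed eigendecomposition from
#'   \code{eigen(A, symmetric = TRUE)}.
#' @param ridge diagonal ridge ensuring a PSD decomposition (default 1e-6).
#' @return a \linkS4class{VarCompEstimate}.
#' @export
remlUnivariate <- function(y, grm, ridge = 1e-6) {
    es <- if (methods::is(grm, "Grm")) grmEigenDecomp(grm, ridge) else grm
    d <- es$values
    n <- length(y)
    if (length(d) != n) stop("GRM dimension does not match y")
    z <- as.numeric(crossprod(es$vectors, y))
    z2 <- z^2
    profLL <- function(h) {
        v <- h * d + (1 - h)
        tau <- mean(z2 / v)
        -0.5 * (n * log(2 * pi * tau) + sum(log(v)) + n)
    }
    opt <- optimize(profLL, c(0, 1), maximum = TRUE, tol = 1e-9)
    ## the optimizer never lands exactly on the ends; check the boundary
    h <- opt$maximum
    ll <- opt$objective
    if (profLL(0) >= ll) { h <- 0; ll <- profLL(0) }
    if (profLL(1 - 1e-12) > ll) { h <- 1; ll <- profLL(1 - 1e-12) }
    tau <- mean(z2 / (h * d + (1 - h)))
    sigmaG <- h * tau
    sigmaE <- (1 - h) * tau
    s <- sigmaG * d + sigmaE
    ## expected information in (sigma_g^2, sigma_e^2)
    F11 <- 0.5 * sum(d^2 / s^2)
    F12 <- 0.5 * sum(d / s^2)
    F22 <- 0.5 * sum(1 / s^2)
    Finv <- solve(matrix(c(F11, F12, F12, F22), 2, 2))
    grad <- c(sigmaE, -sigmaG) / tau^2
    seVg <- sqrt(drop(t(grad) %*% Finv %*% grad))
    ll0 <- profLL(0)
    chi <- max(0, 2 * (ll - ll0))
    pLrt <- if (chi <= 0) 1 else 0.5 * chisqTail(chi, 1)
    methods::new("VarCompEstimate", vg = h, seVg = seVg, sigmaG = sigmaG,
                 sigmaE = sigmaE, loglik = ll, pLrt = pLrt,
                 boundary = (h < 1e-6 || h > 1 - 1e-6),
                 n = as.integer(n))
}

## --- bivariate machinery ---------------------------------------------------

## After rotation by the GRM eigenvectors the two rotated traits are
## independent across eigen-index i with 2x2 covariance d_i * G + E.
## theta = (G11, G12, G22, E11, E12, E22); `free` masks fixed-at-zero
## entries (used for the rg = 0 constrained fit).

bivSigmaParts <- function(theta, d) {
    list(a = theta[1] * d + theta[4],
         b = theta[2] * d + theta[5],
         c = theta[3] * d + theta[6])
}

bivLogLik <- function(theta, d, z1, z2) {
    if (any(theta[c(1, 3, 4, 6)] < 0)) return(-Inf)  # variances stay >= 0
    s <- bivSigmaParts(theta, d)
    det <- s$a * s$c - s$b^2
    if (any(s$a <= 0) || any(s$c <= 0) || any(det <= 1e-300)) return(-Inf)
    quad <- (s$c * z1^2 - 2 * s$b * z1 * z2 + s$a * z2^2) / det
    -0.5 * sum(log(det) + quad) - length(d) * log(2 * pi)
}

bivScoreInfo <- function(theta, d, z1, z2) {
    s <- bivSigmaParts(theta, d)
    det <- s$a * s$c - s$b^2
    p <- s$c / det; q <- -s$b / det; r <- s$a / det
    u1 <- p * z1 + q * z2
    u2 <- q * z1 + r * z2
    ## per-parameter multiplier and basis-matrix type (1 = e11, 2 = sym12,
    ## 3 = e22)
    fs <- list(d, d, d, 1, 1, 1)
    mt <- c(1L, 2L, 3L, 1L, 2L, 3L)
    trv <- list(p, 2 * q, r)
    qfv <- list(u1^2, 2 * u1 * u2, u2^2)
    score <- vapply(1:6, function(k)
        -0.5 * sum(fs[[k]] * (trv[[mt[k]]] - qfv[[mt[k]]])), numeric(1))
    Tfun <- function(i, j) {
        ij <- paste(sort(c(i, j)), collapse = "")
        switch(ij,
               "11" = p^2, "12" = 2 * p * q, "13" = q^2,
               "22" = 2 * (p * r + q^2), "23" = 2 * q * r, "33" = r^2)
    }
    Fi <- matrix(0, 6, 6)
    for (k in 1:6) for (j in k:6) {
        Fi[k, j] <- Fi[j, k] <-
            0.5 * sum(fs[[k]] * fs[[j]] * Tfun(mt[k], mt[j]))
    }
    list(score = score, info = Fi)
}

bivFit <- function(d, z1, z2, free = rep(TRUE, 6), tol = 1e-6,
                   maxIter = 200L) {
    theta <- c(0.5 * var(z1), 0, 0.5 * var(z2),
               0.5 * var(z1), 0, 0.5 * var(z2))
    theta[!free] <- 0
    ll <- bivLogLik(theta, d, z1, z2)
    converged <- FALSE
    it <- 0L
    for (it in seq_len(maxIter)) {
        si <- bivScoreInfo(theta, d, z1, z2)
        Fi <- si$info[free, free, drop = FALSE]
        sc <- si$score[free]
        step <- tryCatch(solve(Fi + diag(1e-10, nrow(Fi)), sc),
                         error = function(e) NULL)
        if (is.null(step)) break
        stalled <- TRUE
        for (half in 0:30) {
            cand <- theta
            cand[free] <- theta[free] + step / 2^half
            llNew <- bivLogLik(cand, d, z1, z2)
            if (is.finite(llNew) && llNew >= ll - 1e-12) {
                stalled <- FALSE
                break
            }
        }
        if (stalled) { converged <- TRUE; break }  # boundary stationary point
        delta <- llNew - ll
        theta <- cand
        ll <- llNew
        if (abs(delta) < tol) { converged <- TRUE; break }
    }
    si <- bivScoreInfo(theta, d, z1, z2)
    list(theta = theta, loglik = ll, converged = converged,
         iterations = it, info = si$info)
}

#' Bivariate GREML: genetic and residual correlation between two traits
#'
#' Maximum likelihood on the zero-mean bivariate model vec(Y) ~
#' N(0, G (x) A + E (x) I), where G and E are the 2x2 genetic and residual
#' covariance matrices. Rotation by the eigenvectors of A makes
#' observations independent across eigen-index with covariance
#' d_i * G + E, and the six parameters are estimated by Fisher scoring with
#' step-halving (log-likelihood monotone by construction). Correlation SEs
#' use the delta method on the inverse expected information; the test of
#' rg = 0 is a 1-df LRT against the fit with the genetic covariance fixed
#' at zero.
#'
#' @param Y n x 2 matrix of standardized residual traits (columns named).
#' @param grm a \linkS4class{Grm} or precomputed eigendecomposition.
#' @param ridge diagonal ridge (default 1e-6).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter maximum scoring iterations (default 200).
#' @return a \linkS4class{BivarCompEstimate}.
#' @export
remlBivariate <- function(Y, grm, ridge = 1e-6, tol = 1e-6,
                          maxIter = 200L) {
    Y <- as.matrix(Y)
    if (ncol(Y) != 2) stop("Y must have exactly two trait columns")
    if (anyNA(Y)) stop("complete cases required; subset before fitting")
    es <- if (methods::is(grm, "Grm")) grmEigenDecomp(grm, ridge) else grm
    d <- es$values
    if (length(d) != nrow(Y)) stop("GRM dimension does not match Y")
    z1 <- as.numeric(crossprod(es$vectors, Y[, 1]))
    z2 <- as.numeric(crossprod(es$vectors, Y[, 2]))
    fit <- bivFit(d, z1, z2, tol = tol, maxIter = maxIter)
    th <- fit$theta
    ## a correlation is undefined when a variance component is pinned at 0
    rgRaw <- if (th[1] <= 1e-12 || th[3] <= 1e-12) 0
             else th[2] / sqrt(th[1] * th[3])
    reRaw <- if (th[4] <= 1e-12 || th[6] <= 1e-12) 0
             else th[5] / sqrt(th[4] * th[6])
    if (!fit$converged) {
        ## a correlation diverging to +-1 sends the likelihood to the
        ## boundary without ever meeting the tolerance; report it clipped
        ## rather than failing
        if (max(abs(rgRaw), abs(reRaw)) <= 1 - 1e-3)
            stop("bivariate REML did not converge after ", fit$iterations,
                 " iterations (loglik ", signif(fit$loglik, 8),
                 "; theta ", paste(signif(th, 4), collapse = ", "), ")")
    }
    G <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
    E <- matrix(c(th[4], th[5], th[5], th[6]), 2, 2)
    rgHat <- rgRaw
    reHat <- reRaw
    clipped <- abs(rgHat) > 1 || abs(reHat) > 1
    rgC <- max(-1, min(1, rgHat))
    reC <- max(-1, min(1, reHat))
    V <- tryCatch(solve(fit$info + diag(1e-10, 6)),
                  error = function(e) matrix(NA_real_, 6, 6))
    gradRg <- c(-rgHat / (2 * th[1]), 1 / sqrt(th[1] * th[3]),
                -rgHat / (2 * th[3]), 0, 0, 0)
    gradRe <- c(0, 0, 0, -reHat / (2 * th[4]), 1 / sqrt(th[4] * th[6]),
                -reHat / (2 * th[6]))
    seRg <- sqrt(drop(t(gradRg) %*% V %*% gradRg))
    seRe <- sqrt(drop(t(gradRe) %*% V %*% gradRe))
    ## rg = 0: refit with the genetic covariance pinned at zero
    fit0 <- bivFit(d, z1, z2, free = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
                   tol = tol, maxIter = maxIter)
    chi <- max(0, 2 * (fit$loglik - fit0$loglik))
    methods::new("BivarCompEstimate", G = G, E = E, rg = rgC, re = reC,
                 seRg = seRg, seRe = seRe, pRg0 = chisqTail(chi, 1),
                 loglik = fit$loglik,
                 traits = colnames(Y) %||% c("trait1", "trait2"),
                 n = nrow(Y), converged = fit$converged,
                 iterations = as.integer(fit$iterations),
                 clipped = clipped)
}

#' Phenotypic correlation with its large-sample standard error
#'
#' Pearson correlation of two standardized residual traits with
#' SE = sqrt((1 - r^2) / (n - 2)).
#'
#' @param y1,y2 numeric vectors of equal length (>= 3).
#' @return list: r, se, n.
#' @export
phenotypicCorrelation <- function(y1, y2) {
    if (length(y1) != length(y2) || length(y1) < 3)
        stop("y1 and y2 must have equal length >= 3")
    if (sd(y1) == 0 || sd(y2) == 0) stop("zero-variance input")
    r <- cor(y1, y2)
    n <- length(y1)
    list(r = r, se = sqrt((1 - r^2) / (n - 2)), n = n)
}
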