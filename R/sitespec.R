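## Trivariate-normal modelling of one SNP's standardized effect across
## three skeletal sites, the constrained-vs-free likelihood-ratio test and
## the Fisher combination across cohorts.

mvnCholPD <- function(sigma) {
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch) ||
        min(diag(ch))^2 < 1e-10 * max(diag(sigma)))
        stop("residual covariance is not positive definite ",
             "(duplicated or collinear trait columns?)", call. = FALSE)
    ch
}

mvnLogLik <- function(n, sigma) {
    ## log-likelihood at the ML residual covariance (quadratic term = k*n)
    k <- ncol(sigma)
    ch <- mvnCholPD(sigma)
    -0.5 * n * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + k)
}

prepareYg <- function(Y, g) {
    Y <- as.matrix(Y)
    if (is.null(colnames(Y))) colnames(Y) <- c("LL", "UL", "SK")
    keep <- complete.cases(Y, g)
    Y <- Y[keep, , drop = FALSE]
    g <- g[keep]
    if (nrow(Y) <= 5) stop("need more than 5 complete cases")
    if (var(g) == 0) stop("monomorphic SNP: constant dosage")
    list(Y = Y, g = g)
}

#' Unconstrained trivariate-normal fit for one SNP
#'
#' Maximum-likelihood fit of the saturated mean model: each site's
#' standardized trait is regressed on an intercept and the dosage (the
#' design is identical across equations, so equation-wise OLS gives the ML
#' mean parameters) and the residual covariance is the ML (1/n)
#' cross-product of residuals.
#'
#' @param Y n x 3 matrix of standardized traits (columns LL, UL, SK).
#' @param g dosage vector.
#' @return an \linkS4class{MvnSiteFit} with constraint \code{"full"}.
#' @export
fitMvnFull <- function(Y, g) {
    d <- prepareYg(Y, g); Y <- d$Y; g <- d$g
    n <- nrow(Y)
    gc <- g - mean(g)
    Yc <- sweep(Y, 2, colMeans(Y))
    beta <- as.numeric(crossprod(Yc, gc)) / sum(gc^2)
    names(beta) <- colnames(Y)
    mu <- colMeans(Y) - beta * mean(g)
    R <- Yc - outer(gc, beta)
    sigma <- crossprod(R) / n
    methods::new("MvnSiteFit", mu = mu, beta = beta, sigma = sigma,
                 loglik = mvnLogLik(n, sigma), constraint = "full",
                 freeSite = NA_character_, nParamsMean = 3L,
                 n = as.integer(n), converged = TRUE, iterations = 0L)
}

#' Constrained trivariate-normal fit for one SNP
#'
#' ML under a linear constraint on the slopes: \code{"all_equal"} forces one
#' shared slope across the three sites; \code{"one_free"} lets the slope of
#' \code{freeSite} differ while the other two stay equal. Estimation is by
#' iterated feasible GLS — given the residual covariance the constrained
#' mean parameters solve the GLS normal equations; given the means the
#' covariance is updated as the ML residual cross-product — iterated until
#' the log-likelihood changes by less than \code{tol}. Each half-step
#' maximizes the joint likelihood, so the iteration is monotone.
#'
#' @param Y n x 3 matrix of standardized traits.
#' @param g dosage vector.
#' @param constraint \code{"all_equal"} or \code{"one_free"}.
#' @param freeSite site whose slope is free (required for
#'   \code{"one_free"}).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter maximum iterations (default 200).
#' @param fixedSigma optional known residual covariance: a single GLS solve
#'   against this matrix replaces the iterated fit (the covariance is not
#'   re-estimated). Under a diagonal \code{fixedSigma} the shared slope is
#'   exactly the precision-weighted average of the per-trait OLS slopes.
#' @return an \linkS4class{MvnSiteFit}.
#' @export
fitMvnConstrained <- function(Y, g,
                              constraint = c("all_equal", "one_free"),
                              freeSite = NULL, tol = 1e-8, maxIter = 200L,
                              fixedSigma = NULL) {
    constraint <- match.arg(constraint)
    d <- prepareYg(Y, g); Y <- d$Y; g <- d$g
    n <- nrow(Y)
    sites <- colnames(Y)
    if (constraint == "one_free") {
        if (is.null(freeSite) || !freeSite %in% sites)
            stop("freeSite must name one of: ", paste(sites, collapse = ", "))
        C <- cbind(shared = as.numeric(sites != freeSite),
                   free = as.numeric(sites == freeSite))
    } else {
        C <- cbind(shared = rep(1, 3))
        freeSite <- NA_character_
    }
    gc <- g - mean(g)
    Yc <- sweep(Y, 2, colMeans(Y))
    Sg2 <- sum(gc^2)
    s <- as.numeric(crossprod(Yc, gc))      # sum_i g_i * y_i (3-vector)
    if (!is.null(fixedSigma)) {
        ## known-covariance GLS: one exact solve, no covariance update
        W <- chol2inv(mvnCholPD(fixedSigma))
        theta <- solve(crossprod(C, W %*% C) * Sg2, crossprod(C, W %*% s))
        beta <- as.numeric(C %*% theta)
        R <- Yc - outer(gc, beta)
        ch <- mvnCholPD(fixedSigma)
        quad <- sum(backsolve(ch, t(R), transpose = TRUE)^2)
        ll <- -0.5 * (n * (3 * log(2 * pi) + 2 * sum(log(diag(ch)))) + quad)
        names(beta) <- sites
        mu <- colMeans(Y) - beta * mean(g)
        return(methods::new("MvnSiteFit", mu = mu, beta = beta,
                            sigma = fixedSigma, loglik = ll,
                            constraint = constraint, freeSite = freeSite,
                            nParamsMean = ncol(C), n = as.integer(n),
                            converged = TRUE, iterations = 1L))
    }
    ## start from equation-wise OLS residual covariance
    betaOls <- s / Sg2
    R0 <- Yc - outer(gc, betaOls)
    sigma <- crossprod(R0) / n
    ll <- -Inf
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        W <- chol2inv(chol(sigma))
        theta <- solve(crossprod(C, W %*% C) * Sg2, crossprod(C, W %*% s))
        beta <- as.numeric(C %*% theta)
        R <- Yc - outer(gc, beta)
        sigma <- crossprod(R) / n
        llNew <- mvnLogLik(n, sigma)
        if (llNew < ll - 1e-9)
            stop("iterated GLS decreased the log-likelihood")
        if (is.finite(ll) && llNew - ll < tol) {
            ll <- llNew
            converged <- TRUE
            break
        }
        ll <- llNew
    }
    if (!converged)
        stop("constrained fit did not converge after ", maxIter,
             " iterations (last loglik ", signif(ll, 10), ")")
    names(beta) <- sites
    mu <- colMeans(Y) - beta * mean(g)
    methods::new("MvnSiteFit", mu = mu, beta = beta, sigma = sigma,
                 loglik = ll, constraint = constraint,
                 freeSite = freeSite, nParamsMean = ncol(C),
                 n = as.integer(n), converged = converged,
                 iterations = as.integer(it))
}

#' Select the site whose slope is most different from the other two
#'
#' Operationalized on the full-model estimates as the site maximizing the
#' absolute deviation of its slope from the mean of the other two slopes;
#' ties break by the fixed site order LL, UL, SK.
#'
#' @param fullFit an \linkS4class{MvnSiteFit} with constraint
#'   \code{"full"}.
#' @return the selected site label.
#' @export
selectFreeSite <- function(fullFit) {
    stopifnot(methods::is(fullFit, "MvnSiteFit"))
    b <- siteBetas(fullFit)
    dev <- abs(b - (sum(b) - b) / 2)
    pref <- intersect(c("LL", "UL", "SK"), names(b))
    if (length(pref) == length(b)) dev <- dev[pref]
    names(dev)[which.max(dev)]         # which.max: first maximum wins
}

#' Likelihood-ratio test of site-specific effect size
#'
#' Twice the log-likelihood difference between the one-free and all-equal
#' fits, referred to a 1-df chi-square (upper tail in log space).
#'
#' @param allEqualFit,oneFreeFit nested \linkS4class{MvnSiteFit} objects.
#' @return list: chi (clipped at 0), p.
#' @export
lrtSite <- function(allEqualFit, oneFreeFit) {
    chi <- 2 * (logLik(oneFreeFit) - logLik(allEqualFit))
    if (chi < -1e-6)
        stop("one-free fit has lower likelihood than all-equal fit; ",
             "fits are out of order or unconverged")
    chi <- max(chi, 0)
    list(chi = chi, p = chisqTail(chi, 1))
}

#' Fisher's combined probability test
#'
#' Combines k independent P-values as X = -2 * sum(log p), chi-square with
#' 2k df; the tail is evaluated in log space and stays accurate far below
#' 1e-40.
#'
#' @param p vector of P-values in (0, 1].
#' @return list: x, df, p.
#' @export
fisherCombine <- function(p) {
    if (any(p <= 0))
        stop("zero P-value underflows Fisher's product; ",
             "supply log P-values via the component tests instead")
    if (any(p > 1)) stop("P-values must lie in (0, 1]")
    x <- -2 * sum(log(p))
    df <- 2L * length(p)
    list(x = x, df = df, p = fisherTailP(x, df))
}

#' Upper tail of the Fisher combination statistic
#'
#' @param x combination statistic, -2 * sum(log p).
#' @param df degrees of freedom (2 x number of tests).
#' @return upper-tail chi-square probability.
#' @export
fisherTailP <- function(x, df) chisqTail(x, df)

#' Site-specificity test of one SNP across cohorts
#'
#' Per cohort: fit the full trivariate model, select the site most
#' different from the other two, fit the all-equal and one-free models and
#' form the 1-df LRT; then combine the per-cohort P-values with Fisher's
#' product and flag significance against \code{alpha}. Site selection is
#' per cohort unless \code{freeSite} fixes it globally.
#'
#' @param cohortData named list, one element per cohort, each a list with
#'   \code{Y} (n x 3 standardized traits) and \code{g} (dosage).
#' @param snpId SNP label for the result.
#' @param alpha significance threshold (default 5e-8).
#' @param freeSite optional site label fixing the free site in all cohorts.
#' @return a \linkS4class{SiteSpecResult}.
#' @export
siteSpecificityTest <- function(cohortData, snpId = "snp",
                                alpha = 5e-8, freeSite = NULL) {
    if (!length(cohortData)) stop("at least one cohort required")
    nm <- names(cohortData) %||% paste0("cohort", seq_along(cohortData))
    rows <- vector("list", length(cohortData))
    for (i in seq_along(cohortData)) {
        Y <- cohortData[[i]]$Y
        g <- cohortData[[i]]$g
        full <- fitMvnFull(Y, g)
        fs <- if (is.null(freeSite)) selectFreeSite(full) else freeSite
        eq <- fitMvnConstrained(Y, g, "all_equal")
        fr <- fitMvnConstrained(Y, g, "one_free", freeSite = fs)
        lrt <- lrtSite(eq, fr)
        rows[[i]] <- data.frame(cohort = nm[i], freeSite = fs,
                                chi = lrt$chi, p = lrt$p,
                                stringsAsFactors = FALSE)
    }
    perCohort <- do.call(rbind, rows)
    fc <- fisherCombine(perCohort$p)
    methods::new("SiteSpecResult", snpId = snpId, perCohort = perCohort,
                 fisherX = fc$x, fisherDf = as.integer(fc$df),
                 fisherP = fc$p, alpha = alpha,
                 significant = fc$p < alpha)
}
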