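#' Conditional single-SNP regression
#'
#' Re-estimates a target SNP's effect with other locus SNPs as covariates
#' (individual-level conditioning): multiple OLS of the standardized trait
#' on intercept + target dosage + conditioning dosages. An empty
#' conditioning set reproduces the marginal regression exactly.
#'
#' @param y standardized residual trait vector.
#' @param g target dosage vector.
#' @param conditioning matrix (or vector) of conditioning dosages; columns
#'   should be named by SNP id.
#' @param maxR absolute correlation between target and any conditioning
#'   SNP above which a collinearity error is raised (default 0.999).
#' @param pReference see [dosageRegression()].
#' @return one-row data.frame: beta, se, z, p, n (target coefficient).
#' @export
conditionalRegression <- function(y, g, conditioning = NULL,
                                  maxR = 0.999,
                                  pReference = c("normal", "t")) {
    pReference <- match.arg(pReference)
    if (is.null(conditioning) || NCOL(conditioning) == 0 ||
        length(conditioning) == 0)
        return(dosageRegression(y, g, pReference = pReference))
    Gc <- as.matrix(conditioning)
    if (is.null(colnames(Gc)))
        colnames(Gc) <- paste0("cond", seq_len(ncol(Gc)))
    r <- suppressWarnings(cor(g, Gc))
    bad <- which(abs(r) >= maxR)
    if (length(bad))
        stop("conditioning SNP collinear with target: ",
             paste(colnames(Gc)[bad], collapse = ", "))
    dosageRegression(y, g, extra = Gc, pReference = pReference)
}

#' Meta-analysis of per-cohort conditional records
#'
#' Pools per-cohort conditional effect estimates by inverse-variance
#' fixed-effects meta-analysis (with heterogeneity when k >= 2).
#'
#' @param records data.frame of per-cohort conditional results (columns
#'   beta, se, n).
#' @return one-row data.frame: beta, se, z, p, q, i2, n.
#' @export
conditionalMeta <- function(records) {
    m <- ivwMeta(records$beta, records$se)
    het <- if (nrow(records) >= 2)
        cochranQ(records$beta, records$se, m$beta)
    else list(q = NA_real_, i2 = NA_real_)
    data.frame(beta = m$beta, se = m$se, z = m$z, p = m$p,
               q = het$q, i2 = het$i2, n = sum(records$n))
}

#' Effective number of independent tests in an LD block (Nyholt)
#'
#' Spectral-decomposition estimate: with eigenvalues lambda of the M x M
#' SNP correlation matrix, the observed eigenvalue variance is
#' Var_obs = sum((lambda - 1)^2) / (M - 1) and
#' Meff = 1 + (M - 1) * (1 - Var_obs / M). The locus-wise threshold is
#' 0.05 / Meff.
#'
#' @param ldCor M x M SNP correlation matrix.
#' @param locusId optional locus label.
#' @param alpha family-wise rate to divide (default 0.05).
#' @return list: locusId, mSnps, meff, alphaLocus.
#' @export
nyholtMeff <- function(ldCor, locusId = NA_character_, alpha = 0.05) {
    checkCorrMatrix(ldCor, "ldCor")
    M <- nrow(ldCor)
    if (M == 1)
        return(list(locusId = locusId, mSnps = 1L, meff = 1,
                    alphaLocus = alpha))
    lam <- eigen(ldCor, symmetric = TRUE, only.values = TRUE)$values
    varObs <- sum((lam - 1)^2) / (M - 1)
    meff <- 1 + (M - 1) * (1 - varObs / M)
    list(locusId = locusId, mSnps = as.integer(M), meff = meff,
         alphaLocus = alpha / meff)
}

#' Declare an independent secondary signal
#'
#' TRUE when the conditional meta-analysis P-value reaches the
#' locus-specific multiple-testing threshold (inclusive, matching the
#' P <= threshold convention).
#'
#' @param pConditional conditional meta-analysis P-value.
#' @param threshold list from [nyholtMeff()] (or a bare numeric
#'   threshold).
#' @return logical.
#' @export
declareSecondary <- function(pConditional, threshold) {
    thr <- if (is.list(threshold)) threshold$alphaLocus else threshold
    pConditional <= thr
}
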