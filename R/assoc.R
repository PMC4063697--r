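#' Residualize a trait on covariates and standardize
#'
#' Two-stage trait preparation used throughout the pipeline: the raw trait
#' is regressed by OLS on an intercept plus the chosen covariate set and the
#' residuals are standardized to mean 0, sd 1. Covariate sets follow the
#' skeletal-site convention: appendicular and total-body sites are adjusted
#' for age, sex and weight; the skull substitutes height for weight (its
#' BMD is assumed unaffected by loading-related pathways); a sensitivity
#' set adjusts all sites for age, sex, weight and height.
#'
#' @param phenotypes data.frame with the trait and covariate columns
#'   (AGE, SEX, WEIGHT, HEIGHT).
#' @param trait trait column name (TBLH, LL, UL or SK).
#' @param covariateSet \code{"model0"} (age+sex+weight; age+sex+height for
#'   SK) or \code{"model1a"} (age+sex+weight+height).
#' @param extra optional matrix of additional covariates (e.g. ancestry
#'   PCs), rows aligned with \code{phenotypes}.
#' @return numeric vector of standardized residuals (complete cases; an
#'   attribute \code{"cases"} records the rows used).
#' @export
residualizeStandardize <- function(phenotypes, trait,
                                   covariateSet = c("model0", "model1a"),
                                   extra = NULL) {
    covariateSet <- match.arg(covariateSet)
    covs <- if (covariateSet == "model1a")
        c("AGE", "SEX", "WEIGHT", "HEIGHT")
    else if (trait == "SK") c("AGE", "SEX", "HEIGHT")
    else c("AGE", "SEX", "WEIGHT")
    X <- as.matrix(phenotypes[, covs, drop = FALSE])
    if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
    y <- phenotypes[[trait]]
    cases <- complete.cases(cbind(y, X))
    X <- cbind(1, X[cases, , drop = FALSE])
    if (qr(X)$rank < ncol(X))
        stop("rank-deficient covariate matrix (constant covariate?)")
    fit <- stats::lm.fit(X, y[cases])
    r <- fit$residuals
    r <- r / sd(r)
    attr(r, "cases") <- which(cases)
    r
}

#' Ancestry-informative principal components of a genotype panel
#'
#' Top-k principal components of the centered, variance-standardized
#' genotype matrix (missing calls mean-imputed before standardization).
#' Scores are column-orthogonal; k = 0 returns an empty matrix.
#'
#' @param panel a \linkS4class{DosagePanel}.
#' @param k number of components (< number of individuals).
#' @return n x k matrix of PC scores (columns PC1..PCk).
#' @export
pcCovariates <- function(panel, k) {
    stopifnot(methods::is(panel, "DosagePanel"))
    n <- ncol(panel)
    if (k >= n) stop("k must be smaller than the number of individuals")
    if (k == 0)
        return(matrix(numeric(0), n, 0,
                      dimnames = list(colnames(panel), NULL)))
    X <- dosages(panel)
    if (anyNA(X)) {
        mu <- rowMeans(X, na.rm = TRUE)
        idx <- which(is.na(X), arr.ind = TRUE)
        X[idx] <- mu[idx[, 1]]
    }
    X <- t(scale(t(X)))
    X <- X[apply(is.finite(X), 1, all), , drop = FALSE]
    sv <- svd(t(X), nu = k, nv = 0)
    scores <- sv$u[, seq_len(k), drop = FALSE] %*%
        diag(sv$d[seq_len(k)], k, k)
    dimnames(scores) <- list(colnames(panel), paste0("PC", seq_len(k)))
    scores
}

#' Single-SNP dosage regression
#'
#' OLS of a standardized trait on an intercept, the expected allelic dosage
#' and optional extra covariates. The reported effect is the dosage
#' coefficient in SD per effect-allele copy; the two-sided P comes from the
#' Wald z by default (samples here are in the thousands), switchable to the
#' t reference.
#'
#' @param y standardized residual trait vector.
#' @param g dosage vector (variance must be positive).
#' @param extra optional covariate matrix.
#' @param pReference \code{"normal"} (default) or \code{"t"}.
#' @return one-row data.frame: beta, se, z, p, n.
#' @export
dosageRegression <- function(y, g, extra = NULL,
                             pReference = c("normal", "t")) {
    pReference <- match.arg(pReference)
    if (length(y) != length(g)) stop("length mismatch between y and g")
    keep <- complete.cases(y, g, extra)
    y <- y[keep]; g <- g[keep]
    if (var(g) == 0) stop("monomorphic SNP: zero-variance dosage")
    X <- if (is.null(extra)) cbind(1, g)
         else cbind(1, g, as.matrix(extra)[keep, , drop = FALSE])
    fit <- stats::lm.fit(X, y)
    df <- length(y) - ncol(X)
    s2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    beta <- fit$coefficients[2]
    se <- sqrt(s2 * XtXinv[2, 2])
    z <- beta / se
    p <- if (pReference == "normal") pvalFromZ(z)
         else 2 * stats::pt(abs(z), df, lower.tail = FALSE)
    data.frame(beta = unname(beta), se = unname(se), z = unname(z),
               p = p, n = length(y))
}

#' Genome-wide association scan of one trait in one cohort
#'
#' Residualizes and standardizes the trait, optionally augments the
#' covariates with ancestry PCs, then regresses the standardized residuals
#' on every SNP's dosage. Dosage and trait are projected off the covariates
#' (Frisch-Waugh), so per-SNP fits reduce to closed-form simple OLS and the
#' scan is a single matrix product.
#'
#' @param panel a \linkS4class{DosagePanel} (QC-passing SNPs).
#' @param phenotypes phenotype/covariate data.frame aligned with the panel
#'   columns (matched by IID).
#' @param trait trait column to analyse.
#' @param covariateSet see [residualizeStandardize()].
#' @param nPcs number of ancestry PCs to include (default 0).
#' @param gc apply genomic control to the returned records (default FALSE).
#' @return data.frame of association records: MarkerName, Allele1, Allele2,
#'   Freq1, Effect, StdErr, Z, P, N, trait, cohort; attribute
#'   \code{"lambdaGC"} carries the inflation factor of the uncorrected scan.
#' @export
assocScan <- function(panel, phenotypes, trait,
                      covariateSet = "model0", nPcs = 0, gc = FALSE) {
    stopifnot(methods::is(panel, "DosagePanel"))
    ord <- match(colnames(panel), phenotypes$IID)
    if (anyNA(ord)) stop("phenotypes missing for some panel individuals")
    ph <- phenotypes[ord, , drop = FALSE]
    pcs <- if (nPcs > 0) pcCovariates(panel, nPcs) else NULL
    y <- residualizeStandardize(ph, trait, covariateSet, extra = pcs)
    cases <- attr(y, "cases")
    D <- dosages(panel)[, cases, drop = FALSE]
    if (anyNA(D)) {
        mu <- rowMeans(D, na.rm = TRUE)
        idx <- which(is.na(D), arr.ind = TRUE)
        D[idx] <- mu[idx[, 1]]
    }
    n <- length(y)
    ## project dosages off the covariates actually used for y
    covs <- if (covariateSet == "model1a")
        c("AGE", "SEX", "WEIGHT", "HEIGHT")
    else if (trait == "SK") c("AGE", "SEX", "HEIGHT")
    else c("AGE", "SEX", "WEIGHT")
    X <- cbind(1, as.matrix(ph[cases, covs, drop = FALSE]))
    if (!is.null(pcs)) X <- cbind(X, pcs[cases, , drop = FALSE])
    Q <- qr.Q(qr(X))
    Dt <- D - (D %*% Q) %*% t(Q)            # residualized dosages
    gss <- rowSums(Dt^2)
    keep <- gss > 1e-10
    gy <- as.numeric(Dt %*% y)
    beta <- gy / gss
    dfres <- n - ncol(X) - 1L
    rss <- sum(y^2) - beta * gy             # y already orthogonal to X
    s2 <- pmax(rss, 0) / dfres
    se <- sqrt(s2 / gss)
    z <- beta / se
    p <- pvalFromZ(z)
    eaf <- rowMeans(D) / 2
    rec <- data.frame(
        MarkerName = rownames(panel),
        Allele1 = SummarizedExperiment::rowData(panel)$EA,
        Allele2 = SummarizedExperiment::rowData(panel)$NEA,
        Freq1 = eaf, Effect = beta, StdErr = se, Z = z, P = p, N = n,
        trait = trait, cohort = cohortId(panel) %||% NA_character_,
        stringsAsFactors = FALSE)
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
    lam <- lambdaGC(rec$Z^2)
    if (gc) rec <- gcCorrect(rec, lam$lambda)
    attr(rec, "lambdaGC") <- lam$lambda
    rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic-control inflation factor
#'
#' lambda_GC = median observed association chi-square divided by 0.45494,
#' the median of the 1-df chi-square distribution.
#'
#' @param chisq vector of 1-df chi-square statistics (e.g. z^2); or supply
#'   \code{p} instead.
#' @param p optional vector of two-sided P-values, converted to chi-squares.
#' @return list with \code{lambda} and \code{corrected} (TRUE when
#'   lambda > 1, i.e. correction would rescale).
#' @export
lambdaGC <- function(chisq = NULL, p = NULL) {
    if (is.null(chisq)) {
        if (is.null(p)) stop("supply chisq or p")
        chisq <- qchisq(p, df = 1, lower.tail = FALSE)
    }
    if (!length(chisq)) stop("at least one statistic required")
    lam <- median(chisq) / qchisq(0.5, df = 1, lower.tail = FALSE)
    list(lambda = lam, corrected = lam > 1)
}

#' Apply genomic control to association records
#'
#' When lambda > 1 each chi-square is divided by lambda — equivalently the
#' standard error is inflated by sqrt(lambda) — and P recomputed; when
#' lambda <= 1 records are returned unchanged (no deflation).
#'
#' @param records data.frame from [assocScan()] (columns Effect, StdErr).
#' @param lambda inflation factor.
#' @return corrected records.
#' @export
gcCorrect <- function(records, lambda) {
    if (lambda <= 1) return(records)
    records$StdErr <- records$StdErr * sqrt(lambda)
    records$Z <- records$Effect / records$StdErr
    records$P <- pvalFromZ(records$Z)
    records
}
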