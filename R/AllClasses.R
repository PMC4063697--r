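#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats pchisq pnorm qchisq optimize rnorm runif rbinom sd var cor
#'   coef lm median complete.cases setNames
#' @importFrom utils read.delim write.table
NULL

#' DosagePanel: per-cohort SNP-by-individual expected allelic dosages
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' named \code{"dosage"} (rows = SNPs, columns = individuals; values are
#' expected effect-allele counts in [0, 2], \code{NA} = missing call).
#' \code{rowData} carries SNP metadata (\code{CHR}, \code{POS}, \code{EA},
#' \code{NEA}); the cohort label is stored in \code{metadata(x)$cohort}.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @export
setClass("DosagePanel", contains = "SummarizedExperiment")

setValidity("DosagePanel", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        dd <- d[!is.na(d)]
        if (length(dd) && (min(dd) < 0 || max(dd) > 2))
            msg <- c(msg, "dosages must lie in [0, 2]")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("CHR", "POS", "EA", "NEA")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData must contain: ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Genetic relationship matrix
#'
#' Symmetric n-by-n matrix of genome-wide allele-sharing coefficients
#' (GCTA-style estimator), with the individual ids and the number of SNPs
#' that entered the average.
#'
#' @slot k symmetric numeric matrix.
#' @slot ids character vector of individual ids (row/col order of \code{k}).
#' @slot mSnps integer, number of SNPs used.
#' @export
setClass("Grm", representation(k = "matrix", ids = "character",
                               mSnps = "integer"))

setValidity("Grm", function(object) {
    msg <- character()
    if (nrow(object@k) != ncol(object@k))
        msg <- c(msg, "k must be square")
    if (length(object@ids) != nrow(object@k))
        msg <- c(msg, "length(ids) must equal nrow(k)")
    if (any(!is.finite(object@k)))
        msg <- c(msg, "k must be finite")
    if (nrow(object@k) > 1 &&
        max(abs(object@k - t(object@k))) > 1e-8)
        msg <- c(msg, "k must be symmetric")
    if (length(msg)) msg else TRUE
})

#' Trivariate-normal mean-model fit for one SNP
#'
#' Maximum-likelihood fit of a 3-trait multivariate normal with per-trait
#' intercepts and per-site dosage slopes, possibly under an equality
#' constraint on the slopes.
#'
#' @slot mu named 3-vector of intercepts.
#' @slot beta named 3-vector of per-site standardized slopes.
#' @slot sigma 3x3 ML residual covariance.
#' @slot loglik log-likelihood at the optimum.
#' @slot constraint one of \code{"full"}, \code{"all_equal"}, \code{"one_free"}.
#' @slot freeSite site left free under \code{"one_free"}, otherwise \code{NA}.
#' @slot nParamsMean number of free mean-model slope parameters.
#' @slot n number of complete cases used.
#' @slot converged,iterations iterated-GLS convergence diagnostics.
#' @export
setClass("MvnSiteFit",
         representation(mu = "numeric", beta = "numeric", sigma = "matrix",
                        loglik = "numeric", constraint = "character",
                        freeSite = "character", nParamsMean = "integer",
                        n = "integer", converged = "logical",
                        iterations = "integer"))

#' Site-specificity test result for one SNP
#'
#' Per-cohort likelihood-ratio statistics for "slopes differ across skeletal
#' sites", combined across cohorts by Fisher's product of P-values.
#'
#' @slot snpId SNP identifier.
#' @slot perCohort data.frame with columns cohort, freeSite, chi, p.
#' @slot fisherX Fisher combination statistic, -2*sum(log p).
#' @slot fisherDf degrees of freedom, 2 x number of cohorts.
#' @slot fisherP upper-tail chi-square P of \code{fisherX}.
#' @slot alpha significance threshold used.
#' @slot significant \code{fisherP < alpha}.
#' @export
setClass("SiteSpecResult",
         representation(snpId = "character", perCohort = "data.frame",
                        fisherX = "numeric", fisherDf = "integer",
                        fisherP = "numeric", alpha = "numeric",
                        significant = "logical"))

#' Univariate REML variance-component estimate
#'
#' @slot vg proportion of variance tagged by the SNPs (SNP-heritability).
#' @slot seVg standard error of \code{vg}.
#' @slot sigmaG,sigmaE genetic and residual variance components.
#' @slot loglik REML log-likelihood at the optimum.
#' @slot pLrt P-value for vg = 0 (0.5:0.5 mixture of chi0 and chi1).
#' @slot boundary TRUE when the estimate lies on the parameter boundary.
#' @slot n sample size.
#' @export
setClass("VarCompEstimate",
         representation(vg = "numeric", seVg = "numeric", sigmaG = "numeric",
                        sigmaE = "numeric", loglik = "numeric",
                        pLrt = "numeric", boundary = "logical",
                        n = "integer"))

#' Bivariate REML variance-component estimate
#'
#' @slot G,E 2x2 genetic and residual covariance matrices.
#' @slot rg,re genetic and residual correlations.
#' @slot seRg,seRe delta-method standard errors.
#' @slot pRg0 LRT P-value for rg = 0 (chi-square 1 df).
#' @slot loglik log-likelihood at the optimum.
#' @slot traits the two trait labels.
#' @slot n sample size.
#' @slot converged,iterations Fisher-scoring diagnostics.
#' @slot clipped TRUE when a correlation exceeded |1| and was clipped.
#' @export
setClass("BivarCompEstimate",
         representation(G = "matrix", E = "matrix", rg = "numeric",
                        re = "numeric", seRg = "numeric", seRe = "numeric",
                        pRg0 = "numeric", loglik = "numeric",
                        traits = "character", n = "integer",
                        converged = "logical", iterations = "integer",
                        clipped = "logical"))

## ---- show methods ---------------------------------------------------------

setMethod("show", "DosagePanel", function(object) {
    cat("DosagePanel:", nrow(object), "SNPs x", ncol(object), "individuals\n")
    ch <- S4Vectors::metadata(object)$cohort
    if (!is.null(ch)) cat("  cohort:", ch, "\n")
    callNextMethod()
})

setMethod("show", "Grm", function(object) {
    cat("Grm:", nrow(object@k), "individuals, built from",
        object@mSnps, "SNPs\n")
    od <- object@k[upper.tri(object@k)]
    if (length(od))
        cat(sprintf("  off-diagonal mean %.4g, range [%.4g, %.4g]\n",
                    mean(od), min(od), max(od)))
})

setMethod("show", "MvnSiteFit", function(object) {
    cat(sprintf("MvnSiteFit (%s%s), n = %d, logLik = %.4f\n",
                object@constraint,
                if (!is.na(object@freeSite))
                    paste0(": ", object@freeSite) else "",
                object@n, object@loglik))
    cat("  beta:", paste(sprintf("%s = %.4f", names(object@beta),
                                 object@beta), collapse = ", "), "\n")
})

setMethod("show", "SiteSpecResult", function(object) {
    cat(sprintf("SiteSpecResult for %s: X = %.2f (df = %d), P = %.3g%s\n",
                object@snpId, object@fisherX, object@fisherDf, object@fisherP,
                if (object@significant) " *" else ""))
    print(object@perCohort, row.names = FALSE)
})

setMethod("show", "VarCompEstimate", function(object) {
    cat(sprintf(
        "VarCompEstimate: vg = %.3f (SE %.3f), P[vg=0] = %.2g, n = %d%s\n",
        object@vg, object@seVg, object@pLrt, object@n,
        if (object@boundary) " [boundary]" else ""))
})

setMethod("show", "BivarCompEstimate", function(object) {
    cat(sprintf(
        "BivarCompEstimate (%s/%s): rg = %.3f (SE %.3f), re = %.3f (SE %.3f)\n",
        object@traits[1], object@traits[2], object@rg, object@seRg,
        object@re, object@seRe))
    cat(sprintf("  P[rg=0] = %.2g, n = %d%s\n", object@pRg0, object@n,
                if (object@clipped) " [clipped]" else ""))
})
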