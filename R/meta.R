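COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize a pair of per-cohort association records
#'
#' Aligns the second record to the first record's effect allele before
#' meta-analysis: allele swaps negate the effect and flip the frequency;
#' opposite-strand records are complemented first; strand-ambiguous A/T or
#' C/G SNPs are dropped when the minor allele frequency in either cohort
#' exceeds \code{ambiguousMafMax} (frequency can no longer resolve the
#' strand); records whose allele sets cannot be reconciled are dropped.
#'
#' @param a,b one-row data.frames with Allele1, Allele2, Freq1, Effect.
#' @param ambiguousMafMax MAF above which ambiguous SNPs are dropped
#'   (default 0.40).
#' @return list(status = "ok"|"dropped", reason, a, b) with \code{b}
#'   aligned to \code{a} when status is "ok".
#' @export
harmonizeAlleles <- function(a, b, ambiguousMafMax = 0.40) {
    norm <- function(x) toupper(as.character(x))
    a1 <- norm(a$Allele1); a2 <- norm(a$Allele2)
    b1 <- norm(b$Allele1); b2 <- norm(b$Allele2)
    ambiguous <- a2 == unname(COMPLEMENT[a1])
    if (ambiguous) {
        maf <- pmin(c(a$Freq1, b$Freq1), 1 - c(a$Freq1, b$Freq1))
        if (min(maf) > ambiguousMafMax)
            return(list(status = "dropped",
                        reason = "strand-ambiguous at high MAF",
                        a = a, b = b))
    }
    flip <- function(rec) {
        rec$Effect <- -rec$Effect
        rec$Freq1 <- 1 - rec$Freq1
        tmp <- rec$Allele1; rec$Allele1 <- rec$Allele2; rec$Allele2 <- tmp
        rec
    }
    if (b1 == a1 && b2 == a2) {
        ## aligned
    } else if (b1 == a2 && b2 == a1) {
        b <- flip(b)
    } else {
        b1c <- unname(COMPLEMENT[b1]); b2c <- unname(COMPLEMENT[b2])
        if (identical(b1c, a1) && identical(b2c, a2)) {
            b$Allele1 <- a1; b$Allele2 <- a2
        } else if (identical(b1c, a2) && identical(b2c, a1)) {
            b$Allele1 <- a2; b$Allele2 <- a1
            b <- flip(b)
        } else {
            return(list(status = "dropped", reason = "allele mismatch",
                        a = a, b = b))
        }
    }
    list(status = "ok", reason = NA_character_, a = a, b = b)
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Precision-weighted average of cohort effect estimates: weights are
#' 1/se^2, the pooled SE is the reciprocal square root of the total weight
#' and the two-sided P comes from the Wald z evaluated in log space
#' (accurate far below 1e-40).
#'
#' @param beta,se numeric vectors of cohort estimates (all se > 0).
#' @return list: beta, se, z, p.
#' @export
ivwMeta <- function(beta, se) {
    if (!length(beta) || length(beta) != length(se))
        stop("beta and se must be non-empty and of equal length")
    if (any(se <= 0)) stop("all standard errors must be positive")
    w <- 1 / se^2
    bm <- sum(w * beta) / sum(w)
    sm <- 1 / sqrt(sum(w))
    z <- bm / sm
    list(beta = bm, se = sm, z = z, p = pvalFromZ(z))
}

#' Cochran's Q heterogeneity statistic and I-squared
#'
#' Q is the weighted sum of squared deviations of the cohort estimates from
#' the pooled estimate, referred to a chi-square with k-1 df; I-squared
#' re-expresses it as the percentage of variation beyond sampling error,
#' floored at 0.
#'
#' @param beta,se cohort estimates (k >= 2).
#' @param betaMeta pooled estimate; recomputed by [ivwMeta()] when missing.
#' @return list: q, df, pHet, i2 (percentage in [0, 100]).
#' @export
cochranQ <- function(beta, se, betaMeta = NULL) {
    if (length(beta) < 2) stop("at least two estimates required")
    if (is.null(betaMeta)) betaMeta <- ivwMeta(beta, se)$beta
    w <- 1 / se^2
    q <- sum(w * (beta - betaMeta)^2)
    df <- length(beta) - 1L
    i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
    list(q = q, df = df, pHet = chisqTail(q, df), i2 = i2)
}

#' Genome-wide significance flag
#'
#' @param p P-value(s) in (0, 1].
#' @param alpha threshold (default 5e-8); significance is strict
#'   (\code{p < alpha}).
#' @return logical vector.
#' @export
gwsFlag <- function(p, alpha = 5e-8) p < alpha

#' Fixed-effects meta-analysis of per-cohort summary statistics
#'
#' Joins two or more cohorts' association records on MarkerName, harmonizes
#' alleles to the first cohort, optionally applies per-cohort genomic
#' control (METAL's "genomic control on" semantics: each input is corrected
#' before pooling, never the pooled statistic), and emits one meta record
#' per SNP with heterogeneity columns.
#'
#' @param cohorts list of association record data.frames (columns
#'   MarkerName, Allele1, Allele2, Freq1, Effect, StdErr, P, N).
#' @param gcInput apply genomic control per cohort first (default TRUE).
#' @param alpha genome-wide significance threshold (default 5e-8).
#' @param ambiguousMafMax see [harmonizeAlleles()].
#' @return data.frame of meta records: MarkerName, Allele1, Allele2, Freq1
#'   (sample-size-weighted), Effect, StdErr, Z, P, Direction, HetQ, HetDf,
#'   HetISq, HetPVal, N, GWS; attribute \code{"dropped"} lists harmonization
#'   drops.
#' @export
metaAnalyze <- function(cohorts, gcInput = TRUE, alpha = 5e-8,
                        ambiguousMafMax = 0.40) {
    if (length(cohorts) < 2) stop("need at least two cohorts")
    if (gcInput)
        cohorts <- lapply(cohorts, function(cc)
            gcCorrect(cc, lambdaGC((cc$Effect / cc$StdErr)^2)$lambda))
    ref <- cohorts[[1]]
    common <- Reduce(intersect, lapply(cohorts, `[[`, "MarkerName"))
    dropped <- data.frame(MarkerName = character(), reason = character(),
                          stringsAsFactors = FALSE)
    out <- vector("list", length(common))
    for (i in seq_along(common)) {
        mk <- common[i]
        recs <- lapply(cohorts, function(cc)
            cc[match(mk, cc$MarkerName), , drop = FALSE])
        ok <- TRUE
        for (j in seq_along(recs)[-1]) {
            h <- harmonizeAlleles(recs[[1]], recs[[j]], ambiguousMafMax)
            if (h$status != "ok") {
                dropped <- rbind(dropped, data.frame(
                    MarkerName = mk, reason = h$reason,
                    stringsAsFactors = FALSE))
                ok <- FALSE
                break
            }
            recs[[j]] <- h$b
        }
        if (!ok) next
        beta <- vapply(recs, `[[`, numeric(1), "Effect")
        se <- vapply(recs, `[[`, numeric(1), "StdErr")
        nn <- vapply(recs, `[[`, numeric(1), "N")
        fq <- vapply(recs, `[[`, numeric(1), "Freq1")
        m <- ivwMeta(beta, se)
        h2 <- cochranQ(beta, se, m$beta)
        out[[i]] <- data.frame(
            MarkerName = mk,
            Allele1 = recs[[1]]$Allele1, Allele2 = recs[[1]]$Allele2,
            Freq1 = sum(fq * nn) / sum(nn),
            Effect = m$beta, StdErr = m$se, Z = m$z, P = m$p,
            Direction = paste(ifelse(beta >= 0, "+", "-"), collapse = ""),
            HetQ = h2$q, HetDf = h2$df, HetISq = h2$i2, HetPVal = h2$pHet,
            N = sum(nn), GWS = gwsFlag(m$p, alpha),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(res)) res <- data.frame()
    rownames(res) <- NULL
    attr(res, "dropped") <- dropped
    res
}
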