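#' Cohort specification for the genotype simulator
#'
#' Describes one cohort of unrelated children genotyped on a SNP panel:
#' sample size, number of SNPs, the allele-frequency window the SNPs are
#' drawn from, optional imputation-like dosage jitter and optional missing
#' calls. The defaults emulate a paediatric DXA cohort at desk scale.
#'
#' @param cohortId label for the cohort.
#' @param nIndividuals number of individuals (>= 2).
#' @param nSnps number of SNPs (>= 1).
#' @param mafRange length-2 numeric in (0, 0.5], the window the per-SNP
#'   effect-allele frequencies are drawn from uniformly.
#' @param dosageNoiseSd nonnegative sd of Gaussian jitter added to hard
#'   genotypes (then clipped to [0, 2]); 0 = hard genotypes (default).
#' @param missingRate proportion of calls set missing at random (default 0).
#' @param seed integer seed making the panel reproducible.
#' @return a list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(cohortId, nIndividuals, nSnps,
                       mafRange = c(0.05, 0.5), dosageNoiseSd = 0,
                       missingRate = 0, seed = 1L) {
    if (nIndividuals < 2) stop("nIndividuals must be >= 2")
    if (nSnps < 1) stop("nSnps must be >= 1")
    if (length(mafRange) != 2 || any(!is.finite(mafRange)) ||
        mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
        stop("mafRange must lie within (0, 0.5] with min <= max")
    if (dosageNoiseSd < 0) stop("dosageNoiseSd must be nonnegative")
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must be in [0, 1)")
    structure(list(cohortId = as.character(cohortId),
                   nIndividuals = as.integer(nIndividuals),
                   nSnps = as.integer(nSnps),
                   mafRange = as.numeric(mafRange),
                   dosageNoiseSd = as.numeric(dosageNoiseSd),
                   missingRate = as.numeric(missingRate),
                   seed = as.integer(seed)),
              class = "CohortSpec")
}

#' Multi-trait genetic architecture for the phenotype simulator
#'
#' Generating model for four correlated BMD traits (total-body less head,
#' lower limb, upper limb, skull): each causal SNP carries a 4-vector of
#' standardized allelic effects drawn from a zero-mean multivariate normal
#' with correlation \code{Rg} and per-trait variance \code{h2/nCausal};
#' residuals are multivariate normal with correlation \code{Re} and
#' per-trait variance \code{1 - h2}, so each trait has unit variance before
#' covariates are added.
#'
#' @param traitNames four trait labels (default TBLH, LL, UL, SK).
#' @param h2 per-trait SNP-heritability in [0, 1] (length 4, recycled).
#' @param Rg,Re 4x4 genetic and residual correlation matrices (symmetric,
#'   unit diagonal, positive semi-definite).
#' @param nCausal number of causal SNPs (effects spread over these).
#' @param covariateLoadings 4x4 matrix (traits x AGE,SEX,WEIGHT,HEIGHT) of
#'   coefficients applied to standardized covariates.
#' @return a list of class \code{"TraitArchitecture"}.
#' @seealso [defaultTraitArchitecture()] for the study-condition defaults.
#' @export
traitArchitecture <- function(traitNames = c("TBLH", "LL", "UL", "SK"),
                              h2, Rg, Re, nCausal,
                              covariateLoadings = NULL) {
    k <- length(traitNames)
    h2 <- rep_len(h2, k)
    if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
    checkCorrMatrix(Rg, "Rg")
    checkCorrMatrix(Re, "Re")
    if (nrow(Rg) != k || nrow(Re) != k)
        stop("Rg and Re must be ", k, "x", k)
    if (is.null(covariateLoadings)) {
        ## each trait loads on the size covariate its analysis model
        ## adjusts for: weight for total-body/appendicular sites, height
        ## for the skull (which is insensitive to loading-related weight
        ## pathways) — so the residualized trait keeps genetic proportion
        ## h2 by construction
        covariateLoadings <- matrix(0, k, 4, dimnames = list(
            traitNames, c("AGE", "SEX", "WEIGHT", "HEIGHT")))
        covariateLoadings[, "AGE"] <- 0.3
        covariateLoadings[, "SEX"] <- 0.3
        covariateLoadings[, "WEIGHT"] <- ifelse(traitNames == "SK", 0, 0.5)
        covariateLoadings[, "HEIGHT"] <- ifelse(traitNames == "SK", 0.5, 0)
    }
    structure(list(traitNames = traitNames, h2 = setNames(h2, traitNames),
                   Rg = Rg, Re = Re, nCausal = as.integer(nCausal),
                   covariateLoadings = covariateLoadings),
              class = "TraitArchitecture")
}

#' Default four-site BMD architecture
#'
#' SNP-heritabilities and the genetic/residual correlation structure used as
#' generating study conditions: appendicular sites share most of their
#' genetic architecture (LL/UL rg = 0.78) and residual influences
#' (re = 0.55), the skull is more distinct (rg 0.44-0.58, re 0.20-0.29) and
#' has the highest SNP-heritability (0.51 vs 0.39-0.42). TBLH, a
#' near-composite of the limb sites, is given correspondingly high
#' correlations with them.
#'
#' @param nCausal number of causal SNPs (default 2000).
#' @return a \code{"TraitArchitecture"} list.
#' @export
defaultTraitArchitecture <- function(nCausal = 2000L) {
    tn <- c("TBLH", "LL", "UL", "SK")
    Rg <- matrix(c(1.00, 0.92, 0.90, 0.52,
                   0.92, 1.00, 0.78, 0.44,
                   0.90, 0.78, 1.00, 0.58,
                   0.52, 0.44, 0.58, 1.00), 4, 4,
                 dimnames = list(tn, tn))
    Re <- matrix(c(1.00, 0.90, 0.85, 0.29,
                   0.90, 1.00, 0.55, 0.20,
                   0.85, 0.55, 1.00, 0.24,
                   0.29, 0.20, 0.24, 1.00), 4, 4,
                 dimnames = list(tn, tn))
    traitArchitecture(tn, h2 = c(0.42, 0.40, 0.39, 0.51), Rg = Rg, Re = Re,
                      nCausal = nCausal)
}

#' Simulate a genotype dosage panel
#'
#' Draws, for each SNP, an effect-allele frequency p uniformly from the
#' spec's \code{mafRange}, samples hard genotypes under Hardy-Weinberg
#' proportions (p^2, 2pq, q^2), optionally adds Gaussian dosage jitter
#' (clipped to [0, 2]) and optionally masks calls at random. Bit-identical
#' panels are produced for identical specs.
#'
#' @param spec a [cohortSpec()] object.
#' @param map optional shared SNP map from [snpMap()] so that several
#'   cohorts are "genotyped" on the same markers (required for
#'   meta-analysis); its \code{genFreq} column supplies the sampling
#'   frequencies. When absent a cohort-private map is generated from the
#'   spec.
#' @return a \linkS4class{DosagePanel}.
#' @export
simulateGenotypes <- function(spec, map = NULL) {
    stopifnot(inherits(spec, "CohortSpec"))
    set.seed(spec$seed)
    n <- spec$nIndividuals
    if (is.null(map))
        map <- snpMap(spec$nSnps, spec$mafRange, seed = spec$seed)
    m <- nrow(map)
    p <- map$genFreq
    d <- matrix(rbinom(m * n, 2L, rep(p, n)), m, n)
    storage.mode(d) <- "double"
    if (spec$dosageNoiseSd > 0) {
        d <- d + matrix(rnorm(m * n, sd = spec$dosageNoiseSd), m, n)
        d[d < 0] <- 0
        d[d > 2] <- 2
    }
    if (spec$missingRate > 0)
        d[matrix(runif(m * n) < spec$missingRate, m, n)] <- NA_real_
    rowdat <- S4Vectors::DataFrame(CHR = map$CHR, POS = map$POS,
                                   EA = map$EA, NEA = map$NEA,
                                   genFreq = p)
    iids <- sprintf("%s_id%05d", spec$cohortId, seq_len(n))
    dimnames(d) <- list(map$SNP_ID, iids)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = d), rowData = rowdat,
        colData = S4Vectors::DataFrame(IID = iids, row.names = iids))
    S4Vectors::metadata(se)$cohort <- spec$cohortId
    methods::new("DosagePanel", se)
}

#' Synthetic SNP map
#'
#' Marker identifiers, a toy genomic map (22 autosomes, 100 kb spacing),
#' random biallelic allele pairs and per-SNP population frequencies drawn
#' uniformly from \code{mafRange}. Sharing one map across cohort
#' simulations makes their panels joinable by marker.
#'
#' @param nSnps number of SNPs.
#' @param mafRange frequency window in (0, 0.5].
#' @param seed integer seed.
#' @return data.frame: SNP_ID, CHR, POS, EA, NEA, genFreq.
#' @export
snpMap <- function(nSnps, mafRange = c(0.05, 0.5), seed = 1L) {
    set.seed(seed)
    m <- as.integer(nSnps)
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, m, replace = TRUE)
    nea <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), "")
    chr <- rep(seq_len(22L), length.out = m)
    data.frame(SNP_ID = sprintf("snp%06d", seq_len(m)),
               CHR = chr,
               POS = as.integer(1e5 * (seq_len(m) %/% 22L + 1L)) + chr,
               EA = ea, NEA = nea,
               genFreq = runif(m, mafRange[1], mafRange[2]),
               stringsAsFactors = FALSE)
}

#' Simulate correlated multi-trait phenotypes on a panel
#'
#' Implements the generating model of [traitArchitecture()]: causal SNPs are
#' sampled from the panel, genotypes are standardized, per-SNP effect
#' vectors are multivariate normal across traits with correlation \code{Rg},
#' residuals multivariate normal with correlation \code{Re}; covariates
#' (AGE uniform on a 1-year window around 9.5 y, SEX Bernoulli(0.5),
#' WEIGHT/HEIGHT correlated normals, r = 0.7) are added through the loading
#' matrix so they explain roughly 20-40% of raw trait variance.
#'
#' @param panel a \linkS4class{DosagePanel} (complete dosages required for
#'   causal SNPs; missing calls are mean-imputed for the genetic values).
#' @param arch a [traitArchitecture()] object.
#' @param seed integer seed.
#' @return data.frame with IID, AGE, SEX, WEIGHT, HEIGHT and one column per
#'   trait; attributes \code{geneticValues} and \code{residualValues} carry
#'   the latent components for diagnostics.
#' @export
simulatePhenotypes <- function(panel, arch, seed = 1L) {
    stopifnot(methods::is(panel, "DosagePanel"),
              inherits(arch, "TraitArchitecture"))
    if (arch$nCausal > nrow(panel))
        stop("nCausal exceeds the number of SNPs in the panel")
    set.seed(seed)
    n <- ncol(panel)
    k <- length(arch$traitNames)
    causal <- sort(sample(nrow(panel), arch$nCausal))
    X <- dosages(panel)[causal, , drop = FALSE]
    if (anyNA(X)) {
        mu <- rowMeans(X, na.rm = TRUE)
        idx <- which(is.na(X), arr.ind = TRUE)
        X[idx] <- mu[idx[, 1]]
    }
    X <- t(scale(t(X)))                      # standardize each SNP
    X[!is.finite(X)] <- 0                    # monomorphic causal SNPs
    Dg <- sqrt(arch$h2 / arch$nCausal)
    Sg <- (Dg %o% Dg) * arch$Rg
    B <- rmvn(arch$nCausal, Sg)              # per-SNP effect vectors
    Gval <- crossprod(X, B)                  # n x k genetic values
    De <- sqrt(1 - arch$h2)
    Se <- (De %o% De) * arch$Re
    Eval <- rmvn(n, Se)
    ## covariates
    age <- runif(n, 9, 10)
    sex <- rbinom(n, 1L, 0.5)
    wh <- rmvn(n, matrix(c(1, 0.7, 0.7, 1), 2, 2))
    covStd <- cbind(AGE = zstd(age), SEX = sex - mean(sex),
                    WEIGHT = wh[, 1], HEIGHT = wh[, 2])
    Y <- Gval + Eval + covStd %*% t(arch$covariateLoadings)
    colnames(Y) <- arch$traitNames
    out <- data.frame(IID = colnames(panel), AGE = age, SEX = sex,
                      WEIGHT = wh[, 1] * 4 + 32,   # kg-like scale
                      HEIGHT = wh[, 2] * 7 + 138,  # cm-like scale
                      Y, stringsAsFactors = FALSE)
    attr(out, "geneticValues") <- Gval
    attr(out, "residualValues") <- Eval
    attr(out, "causalIndex") <- causal
    out
}

#' Spike a site-specific SNP effect into simulated phenotypes
#'
#' Adds \code{beta[t] * standardized dosage} of one panel SNP to each trait,
#' emulating a variant whose standardized per-allele effect differs across
#' skeletal sites.
#'
#' @param panel a \linkS4class{DosagePanel}.
#' @param phenotypes data.frame from [simulatePhenotypes()] (or any table
#'   with the trait columns).
#' @param snpId SNP identifier present in the panel.
#' @param perTraitBeta named numeric vector of standardized effects; names
#'   select the trait columns to modify.
#' @return the phenotype data.frame with the spiked traits.
#' @export
spikeEffect <- function(panel, phenotypes, snpId, perTraitBeta) {
    stopifnot(methods::is(panel, "DosagePanel"))
    if (!snpId %in% rownames(panel))
        stop("unknown snpId: ", snpId)
    if (is.null(names(perTraitBeta)))
        stop("perTraitBeta must be named by trait")
    g <- dosages(panel)[snpId, ]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    gs <- zstd(g)
    for (tr in names(perTraitBeta)) {
        if (!tr %in% colnames(phenotypes))
            stop("trait column not found: ", tr)
        phenotypes[[tr]] <- phenotypes[[tr]] + perTraitBeta[[tr]] * gs
    }
    phenotypes
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' probability of every heterozygote count no more probable than the
#' observed one is summed (ties included in the tail; no mid-P correction).
#' Probabilities follow the standard levene-haldane distribution evaluated
#' by recurrence.
#'
#' @param nAA,nAa,naa nonnegative genotype counts (total >= 1).
#' @return two-sided exact P-value.
#' @export
hweExactTest <- function(nAA, nAa, naa) {
    if (any(c(nAA, nAa, naa) < 0)) stop("counts must be nonnegative")
    n <- nAA + nAa + naa
    if (n < 1) stop("at least one genotype count required")
    nA <- 2 * nAA + nAa
    na <- 2 * naa + nAa
    R <- min(nA, na)                       # rare allele count
    if (R == 0) return(1)                  # monomorphic: single configuration
    hets <- seq(R %% 2, R, by = 2)
    ## unnormalized probabilities by upward recurrence from the smallest het
    lp <- numeric(length(hets))
    for (i in seq_along(hets)[-1]) {
        h <- hets[i - 1]
        rareHom <- (R - h) / 2
        commHom <- n - h - rareHom
        lp[i] <- lp[i - 1] +
            log(4 * rareHom * commHom) - log((h + 2) * (h + 1))
    }
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    pObs <- pr[match(nAa, hets)]
    if (is.na(pObs)) stop("inconsistent genotype counts")
    sum(pr[pr <= pObs * (1 + 1e-12)])
}

#' Genotype quality control
#'
#' Retains SNPs with minor allele frequency >= \code{mafMin}, call rate
#' >= \code{callRateMin} and Hardy-Weinberg exact P > \code{hweP}; the
#' companion report lists every excluded SNP with all reasons that applied.
#' Frequencies are computed on non-missing calls; the HWE test uses
#' best-guess (rounded) genotypes.
#'
#' @param panel a \linkS4class{DosagePanel}.
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param callRateMin minimum call rate (default 0.95).
#' @param hweP Hardy-Weinberg exclusion threshold: SNPs with exact
#'   P <= \code{hweP} are removed (default 5e-7).
#' @return list with elements \code{panel} (filtered
#'   \linkS4class{DosagePanel}) and \code{report} (data.frame SNP_ID,
#'   reason; one row per excluded SNP, reasons separated by ";").
#' @export
qcFilter <- function(panel, mafMin = 0.01, callRateMin = 0.95,
                     hweP = 5e-7) {
    stopifnot(methods::is(panel, "DosagePanel"))
    d <- dosages(panel)
    callRate <- rowMeans(!is.na(d))
    eaf <- rowMeans(d, na.rm = TRUE) / 2
    maf <- pmin(eaf, 1 - eaf)
    maf[is.nan(maf)] <- 0
    hwe <- vapply(seq_len(nrow(d)), function(i) {
        g <- round(d[i, !is.na(d[i, ])])
        if (!length(g)) return(0)
        hweExactTest(sum(g == 2), sum(g == 1), sum(g == 0))
    }, numeric(1))
    reasons <- lapply(seq_len(nrow(d)), function(i) {
        r <- character()
        if (maf[i] < mafMin) r <- c(r, "MAF")
        if (callRate[i] < callRateMin) r <- c(r, "call rate")
        if (hwe[i] <= hweP) r <- c(r, "HWE")
        r
    })
    drop <- lengths(reasons) > 0
    report <- data.frame(
        SNP_ID = rownames(d)[drop],
        reason = vapply(reasons[drop], paste, "", collapse = ";"),
        stringsAsFactors = FALSE)
    list(panel = panel[!drop, ], report = report)
}
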