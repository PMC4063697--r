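test_that("GRM matches the hand-evaluated estimator on a 5 x 3 toy panel", {
    d <- matrix(c(0, 1, 2, 1, 1,
                  2, 2, 1, 0, 1,
                  1, 0, 1, 2, 2), nrow = 3, byrow = TRUE)
    storage.mode(d) <- "double"
    rownames(d) <- paste0("s", 1:3)
    colnames(d) <- paste0("i", 1:5)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = d),
        rowData = S4Vectors::DataFrame(CHR = 1L, POS = 1:3,
                                       EA = "A", NEA = "G"))
    panel <- methods::new("DosagePanel", se)
    A <- grmMatrix(computeGrm(panel))
    p <- rowMeans(d) / 2
    W <- (d - 2 * p) / sqrt(2 * p * (1 - p))
    oracle <- crossprod(W) / 3
    expect_equal(A, oracle, tolerance = 1e-12)
    ## duplicated individual pairs off-diagonal with the diagonal entries
    d2 <- cbind(d, i6 = d[, 1])
    se2 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = d2),
        rowData = S4Vectors::DataFrame(CHR = 1L, POS = 1:3,
                                       EA = "A", NEA = "G"))
    A2 <- grmMatrix(computeGrm(methods::new("DosagePanel", se2)))
    expect_equal(A2[1, 6], A2[1, 1], tolerance = 1e-12)
    ## monomorphic SNP is an upstream error
    d3 <- rbind(d, mono = rep(2, 5))
    se3 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = d3),
        rowData = S4Vectors::DataFrame(CHR = 1L, POS = 1:4,
                                       EA = "A", NEA = "G"))
    expect_error(computeGrm(methods::new("DosagePanel", se3)),
                 "monomorphic")
})

test_that("GRM off-diagonals centre on zero for unrelated individuals", {
    panel <- simulateGenotypes(cohortSpec("g0", 300, 2000, seed = 80))
    A <- grmMatrix(computeGrm(panel))
    od <- A[upper.tri(A)]
    expect_lt(abs(mean(od)), 3 / sqrt(300 * 2000))
    expect_equal(mean(diag(A)), 1, tolerance = 0.05)
})

test_that("relatedness pruning removes above-cutoff pairs near-optimally", {
    panel <- simulateGenotypes(cohortSpec("pr", 40, 1500, seed = 81))
    grm <- computeGrm(panel)
    ## nothing above an easy cutoff: all retained
    expect_length(pruneRelated(grm, cutoff = 2), 40)
    ## duplicate one individual: exactly one of the pair goes
    A <- grmMatrix(grm)
    A2 <- rbind(cbind(A, A[, 1]), c(A[1, ], A[1, 1]))
    ids2 <- c(grmIds(grm), "dup")
    g2 <- methods::new("Grm", k = A2, ids = ids2, mSnps = grm@mSnps)
    kept <- pruneRelated(g2, cutoff = 0.5)
    expect_length(kept, 40)
    expect_length(setdiff(c(grmIds(grm)[1], "dup"), kept), 1)
    ## random relatedness graph: retained set has no above-cutoff pair and
    ## is within 2 of the exhaustive maximum independent set
    set.seed(82)
    n <- 14
    R <- matrix(0, n, n)
    pairs <- which(upper.tri(R))
    hot <- sample(pairs, 12)
    R[hot] <- 0.5
    R <- R + t(R); diag(R) <- 1
    gg <- methods::new("Grm", k = R, ids = paste0("x", 1:n), mSnps = 10L)
    kept <- pruneRelated(gg, cutoff = 0.025)
    ki <- match(kept, paste0("x", 1:n))
    expect_true(all(abs(R[ki, ki][upper.tri(diag(length(ki)))]) <= 0.025))
    ## brute-force maximum independent set over all subsets
    adj <- R > 0.025; diag(adj) <- FALSE
    best <- 0
    for (mask in 0:(2^n - 1)) {
        mem <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
        if (length(mem) <= best) next
        if (!any(adj[mem, mem])) best <- length(mem)
    }
    expect_gte(length(kept), best - 2)
})

test_that("univariate REML recovers zero and matches a grid-search oracle", {
    panel <- simulateGenotypes(cohortSpec("u0", 800, 1500, seed = 83))
    es <- bonesite:::grmEigenDecomp(computeGrm(panel))
    ## null trait: vg small in most replicates
    small <- sapply(1:10, function(s) {
        set.seed(500 + s)
        vg(remlUnivariate(scale(rnorm(800))[, 1], es))
    })
    expect_gte(mean(small < 0.1), 0.9)
    ## optimum beats a 100-point grid of the variance ratio
    arch <- defaultTraitArchitecture(nCausal = 750L)
    ph <- simulatePhenotypes(panel, arch, seed = 84)
    y <- residualizeStandardize(ph, "SK", "model0")
    est <- remlUnivariate(y, es)
    z2 <- as.numeric(crossprod(es$vectors, y))^2
    n <- length(y)
    grid <- sapply(seq(0.001, 0.999, length.out = 100), function(h) {
        v <- h * es$values + (1 - h)
        tau <- mean(z2 / v)
        -0.5 * (n * log(2 * pi * tau) + sum(log(v)) + n)
    })
    expect_gte(logLik(est), max(grid) - 1e-6)
})

test_that("univariate REML agrees with Haseman-Elston across seeds", {
    he <- reml <- numeric(8)
    for (s in seq_along(he)) {
        panel <- simulateGenotypes(cohortSpec("he", 800, 1500,
                                              seed = 600 + s))
        grm <- computeGrm(panel)
        arch <- defaultTraitArchitecture(nCausal = 750L)
        ph <- simulatePhenotypes(panel, arch, seed = 700 + s)
        y <- residualizeStandardize(ph, "LL", "model0")
        reml[s] <- vg(remlUnivariate(y, grm))
        ## HE regression of phenotype cross-products on GRM off-diagonals
        A <- grmMatrix(grm)
        ut <- upper.tri(A)
        cp <- tcrossprod(y)[ut]
        he[s] <- coef(lm(cp ~ A[ut]))[2]
    }
    mcse <- sd(reml - he) / sqrt(length(he))
    expect_lt(abs(mean(reml - he)), 3 * mcse + 0.02)
})

test_that("bivariate REML reduces to the univariate fits under independence", {
    panel <- simulateGenotypes(cohortSpec("bi0", 700, 1200, seed = 85))
    es <- bonesite:::grmEigenDecomp(computeGrm(panel))
    tn <- c("TBLH", "LL", "UL", "SK")
    Rg <- diag(4); dimnames(Rg) <- list(tn, tn)
    Re <- diag(4); dimnames(Re) <- list(tn, tn)
    arch <- traitArchitecture(tn, h2 = 0.4, Rg = Rg, Re = Re,
                              nCausal = 600L)
    ph <- simulatePhenotypes(panel, arch, seed = 86)
    Y <- cbind(LL = residualizeStandardize(ph, "LL", "model0"),
               UL = residualizeStandardize(ph, "UL", "model0"))
    biv <- remlBivariate(Y, es)
    u1 <- remlUnivariate(Y[, 1], es)
    u2 <- remlUnivariate(Y[, 2], es)
    expect_equal(biv@G[1, 1], u1@sigmaG, tolerance = 0.02)
    expect_equal(biv@G[2, 2], u2@sigmaG, tolerance = 0.02)
    expect_equal(biv@E[1, 1], u1@sigmaE, tolerance = 0.02)
    ## generated independence: correlations near zero
    expect_lt(abs(rg(biv)), 0.35)
    expect_lt(abs(re(biv)), 0.1)
})

test_that("bivariate REML drives a duplicated trait to the unit-correlation boundary", {
    panel <- simulateGenotypes(cohortSpec("dup", 500, 1200, seed = 87))
    es <- bonesite:::grmEigenDecomp(computeGrm(panel))
    arch <- defaultTraitArchitecture(nCausal = 600L)
    ph <- simulatePhenotypes(panel, arch, seed = 88)
    y <- residualizeStandardize(ph, "UL", "model0")
    b <- remlBivariate(cbind(a = y, b = y), es)
    expect_gt(rg(b), 0.999)
    expect_gt(re(b), 0.999)
})

test_that("phenotypic correlation reproduces the variance-decomposition identity", {
    expect_equal(phenotypicCorrelation(1:10, 1:10)$r, 1)
    set.seed(89)
    ind <- phenotypicCorrelation(rnorm(10000), rnorm(10000))
    expect_lt(abs(ind$r), 0.03)
    expect_error(phenotypicCorrelation(rep(1, 10), rnorm(10)), "variance")
    ## h2 rg + (1 - h2) re = 0.64 for the appendicular pair
    rp <- sapply(1:4, function(s) {
        panel <- simulateGenotypes(cohortSpec("rp", 3000, 1000,
                                              seed = 900 + s))
        tn <- c("TBLH", "LL", "UL", "SK")
        RgM <- diag(4); RgM[2, 3] <- RgM[3, 2] <- 0.78
        RgM[1, 2] <- RgM[2, 1] <- RgM[1, 3] <- RgM[3, 1] <- 0.5
        ReM <- diag(4); ReM[2, 3] <- ReM[3, 2] <- 0.55
        ReM[1, 2] <- ReM[2, 1] <- ReM[1, 3] <- ReM[3, 1] <- 0.5
        dimnames(RgM) <- dimnames(ReM) <- list(tn, tn)
        arch <- traitArchitecture(tn, h2 = 0.4, Rg = RgM, Re = ReM,
                                  nCausal = 500L)
        ph <- simulatePhenotypes(panel, arch, seed = 950 + s)
        phenotypicCorrelation(
            residualizeStandardize(ph, "LL", "model0"),
            residualizeStandardize(ph, "UL", "model0"))$r
    })
    expect_equal(mean(rp), 0.4 * 0.78 + 0.6 * 0.55, tolerance = 0.03)
})
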