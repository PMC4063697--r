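test_that("full trivariate fit recovers generating slopes and rejects degenerate input", {
    set.seed(50)
    n <- 50000
    g <- rbinom(n, 2, 0.35)
    gs <- (g - mean(g)) / sd(g)
    Y <- matrix(rnorm(3 * n), n, 3) + outer(gs, rep(0.1, 3))
    colnames(Y) <- c("LL", "UL", "SK")
    fit <- fitMvnFull(Y, g)
    ## slopes are on the standardized-dosage scale used to generate
    expect_true(all(abs(siteBetas(fit) * sd(g) - 0.1) < 0.015))
    expect_error(fitMvnFull(Y, rep(1, n)), "monomorphic")
    ## duplicated trait columns make the covariance singular
    Ybad <- cbind(Y[, 1], Y[, 1], Y[, 3])
    expect_error(fitMvnFull(Ybad, g), "positive definite")
})

test_that("constrained fit matches the diagonal-covariance closed form", {
    set.seed(51)
    n <- 4000
    g <- rbinom(n, 2, 0.3)
    gs <- (g - mean(g)) / sd(g)
    sds <- c(1, 2, 0.5)
    Y <- sapply(1:3, function(t) gs * c(0.1, 0.25, 0.05)[t] +
                                 rnorm(n, sd = sds[t]))
    colnames(Y) <- c("LL", "UL", "SK")
    ## known diagonal covariance: the shared GLS slope is exactly the
    ## precision-weighted average of the per-trait OLS slopes
    S <- diag(sds^2)
    eq <- fitMvnConstrained(Y, g, "all_equal", fixedSigma = S)
    gc <- g - mean(g)
    bOls <- as.numeric(crossprod(sweep(Y, 2, colMeans(Y)), gc)) / sum(gc^2)
    expect_equal(unname(siteBetas(eq)[1]),
                 sum(bOls / sds^2) / sum(1 / sds^2), tolerance = 1e-6)
    ## the iterated fit lands close to the same solution
    eqIt <- fitMvnConstrained(Y, g, "all_equal")
    expect_lt(abs(siteBetas(eqIt)[1] - siteBetas(eq)[1]), 5e-3)
})

test_that("constrained likelihood equals a generic numerical maximizer at n = 50", {
    set.seed(52)
    cd <- simSiteCohort(50, c(0.1, 0.2, 0.0))
    eq <- fitMvnConstrained(cd$Y, cd$g, "all_equal")
    llOracle <- mvn3NumericMax(cd$Y, cd$g)
    expect_gte(logLik(eq), llOracle - 1e-4)
    expect_lte(logLik(eq), llOracle + 1e-4)
})

test_that("log-likelihood nesting holds across constraint levels", {
    set.seed(53)
    for (i in 1:10) {
        cd <- simSiteCohort(400, rnorm(3, 0.1, 0.05))
        full <- fitMvnFull(cd$Y, cd$g)
        eq <- fitMvnConstrained(cd$Y, cd$g, "all_equal")
        fr <- fitMvnConstrained(cd$Y, cd$g, "one_free",
                                freeSite = selectFreeSite(full))
        expect_lte(logLik(eq), logLik(fr) + 1e-6)
        expect_lte(logLik(fr), logLik(full) + 1e-6)
    }
})

test_that("free-site selection follows the most-different rule with fixed tie-break", {
    mk <- function(b) {
        methods::new("MvnSiteFit", mu = setNames(numeric(3),
                                                 c("LL", "UL", "SK")),
                     beta = setNames(b, c("LL", "UL", "SK")),
                     sigma = diag(3), loglik = 0, constraint = "full",
                     freeSite = NA_character_, nParamsMean = 3L, n = 10L,
                     converged = TRUE, iterations = 0L)
    }
    expect_equal(selectFreeSite(mk(c(0.020, 0.187, 0.169))), "LL")
    expect_equal(selectFreeSite(mk(c(0.100, 0.177, 0.088))), "UL")
    expect_equal(selectFreeSite(mk(c(0.1, 0.1, 0.1))), "LL")
})

test_that("the site LRT has the canonical chi-square reference", {
    set.seed(54)
    cd <- simSiteCohort(500, c(0.1, 0.1, 0.1))
    eq <- fitMvnConstrained(cd$Y, cd$g, "all_equal")
    expect_equal(lrtSite(eq, eq)$chi, 0)
    expect_equal(lrtSite(eq, eq)$p, 1)
    expect_equal(bonesite:::chisqTail(3.841459, 1), 0.05, tolerance = 1e-4)
    ## one_free pinned at the shared value reduces to all_equal
    fr <- fitMvnConstrained(cd$Y, cd$g, "one_free", freeSite = "UL")
    expect_gte(logLik(fr), logLik(eq) - 1e-8)
})

test_that("Fisher combination reproduces printed statistics and guards zero", {
    expect_equal(signif(fisherTailP(178.00, 4), 3), 2.00e-37,
                 tolerance = 0.01)
    expect_equal(signif(fisherTailP(69.96, 4), 3), 2.31e-14,
                 tolerance = 0.01)
    fc <- fisherCombine(c(1, 1))
    expect_equal(fc$x, 0)
    expect_equal(fc$p, 1)
    expect_equal(fc$df, 4L)
    expect_error(fisherCombine(c(0.5, 0)), "underflow")
    expect_error(fisherCombine(c(0.5, 1.5)), "lie in")
})

test_that("printed Fisher chi statistics reproduce printed P at 2 significant figures", {
    tab <- siteSpecChiStats()
    big <- tab$CHI >= 15
    recomputed <- fisherTailP(tab$CHI[big], 4)
    expect_equal(signif(recomputed, 2), signif(tab$FISHER_P[big], 2),
                 tolerance = 1e-9)
})

test_that("site-specificity test flags a strong site-specific pattern and not a shared one", {
    ## two cohorts at study scale, spiked with a skull/upper-limb pattern
    hits <- 0L
    set.seed(60)
    for (i in 1:20) {
        cds <- list(a = simSiteCohort(5330, c(0.020, 0.187, 0.169)),
                    b = simSiteCohort(4086, c(0.020, 0.187, 0.169)))
        r <- siteSpecificityTest(cds, snpId = "spiked")
        if (r@significant) hits <- hits + 1L
        expect_equal(r@fisherDf, 4L)
    }
    expect_gte(hits, 19L)
    ## an equal-effect SNP stays below threshold
    nullHits <- 0L
    for (i in 1:20) {
        cds <- list(a = simSiteCohort(2000, rep(0.15, 3)),
                    b = simSiteCohort(1500, rep(0.15, 3)))
        if (fisherP(siteSpecificityTest(cds)) < 5e-8)
            nullHits <- nullHits + 1L
    }
    expect_equal(nullHits, 0L)
    ## single cohort: df = 2
    r1 <- siteSpecificityTest(list(a = simSiteCohort(800, c(0, 0.2, 0.2))))
    expect_equal(r1@fisherDf, 2L)
})
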