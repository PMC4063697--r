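test_that("simulated genotypes follow the requested allele frequencies and HWE", {
    spec <- cohortSpec("hw", 10000, 3, mafRange = c(0.3, 0.3), seed = 42)
    panel <- simulateGenotypes(spec)
    d <- dosages(panel)
    expect_true(all(abs(rowMeans(d) / 2 - 0.3) < 0.02))
    ## p = 0.5: genotype class proportions near (0.25, 0.5, 0.25)
    spec5 <- cohortSpec("hw5", 20000, 2, mafRange = c(0.5, 0.5), seed = 7)
    d5 <- dosages(simulateGenotypes(spec5))
    props <- table(factor(d5[1, ], levels = 0:2)) / ncol(d5)
    expect_equal(as.numeric(props), c(0.25, 0.5, 0.25), tolerance = 0.05)
})

test_that("genotype simulation is reproducible and seed-sensitive", {
    spec <- cohortSpec("rp", 50, 100, seed = 9)
    p1 <- simulateGenotypes(spec)
    p2 <- simulateGenotypes(spec)
    expect_identical(dosages(p1), dosages(p2))
    spec2 <- cohortSpec("rp", 50, 100, seed = 10)
    expect_false(identical(dosages(p1), dosages(simulateGenotypes(spec2))))
})

test_that("invalid cohort specs are rejected", {
    expect_error(cohortSpec("x", 1, 10), "nIndividuals")
    expect_error(cohortSpec("x", 10, 10, mafRange = c(0, 0.5)), "mafRange")
    expect_error(cohortSpec("x", 10, 10, mafRange = c(0.1, 0.6)), "mafRange")
    expect_error(cohortSpec("x", 10, 10, dosageNoiseSd = -1), "dosageNoiseSd")
})

test_that("dosage jitter stays inside [0, 2]", {
    spec <- cohortSpec("j", 200, 50, dosageNoiseSd = 0.5, seed = 3)
    d <- dosages(simulateGenotypes(spec))
    expect_gte(min(d), 0)
    expect_lte(max(d), 2)
})

test_that("phenotype generator recovers the generating correlation structure", {
    ## realized genetic-value correlation for the appendicular pair
    rgs <- res <- numeric(8)
    arch <- defaultTraitArchitecture(nCausal = 1000L)
    for (s in seq_along(rgs)) {
        panel <- simulateGenotypes(cohortSpec("gc", 5000, 1500, seed = s))
        ph <- simulatePhenotypes(panel, arch, seed = 100 + s)
        G <- attr(ph, "geneticValues")
        E <- attr(ph, "residualValues")
        rgs[s] <- cor(G[, "LL"], G[, "UL"])
        res[s] <- cor(E[, "LL"], E[, "UL"])
    }
    expect_lt(abs(mean(rgs) - 0.78), 3 * sd(rgs) / sqrt(length(rgs)) + 0.01)
    expect_lt(abs(mean(res) - 0.55), 3 * sd(res) / sqrt(length(res)) + 0.01)
})

test_that("heritability limits pin the phenotypic correlation", {
    tn <- c("TBLH", "LL", "UL", "SK")
    Rg <- diag(4); Rg[2, 3] <- Rg[3, 2] <- 0.7; dimnames(Rg) <- list(tn, tn)
    Re <- diag(4); Re[2, 3] <- Re[3, 2] <- 0.3; dimnames(Re) <- list(tn, tn)
    zeroLoad <- matrix(0, 4, 4, dimnames = list(tn, c("AGE", "SEX",
                                                      "WEIGHT", "HEIGHT")))
    panel <- simulateGenotypes(cohortSpec("h", 4000, 800, seed = 5))
    ## h2 = 0: phenotype correlation equals the residual correlation
    a0 <- traitArchitecture(tn, h2 = 0, Rg = Rg, Re = Re, nCausal = 400L,
                            covariateLoadings = zeroLoad)
    p0 <- simulatePhenotypes(panel, a0, seed = 6)
    expect_lt(abs(cor(p0$LL, p0$UL) - 0.3), 0.06)
    ## h2 = 1: phenotype correlation equals the genetic correlation
    a1 <- traitArchitecture(tn, h2 = 1, Rg = Rg, Re = Re, nCausal = 400L,
                            covariateLoadings = zeroLoad)
    p1 <- simulatePhenotypes(panel, a1, seed = 7)
    expect_lt(abs(cor(p1$LL, p1$UL) - 0.7), 0.06)
})

test_that("non-PSD correlation matrices are rejected", {
    tn <- c("TBLH", "LL", "UL", "SK")
    bad <- matrix(0.99, 4, 4); diag(bad) <- 1
    bad[1, 2] <- bad[2, 1] <- -0.99
    dimnames(bad) <- list(tn, tn)
    expect_error(traitArchitecture(tn, 0.4, bad, diag(4) + 0, 10),
                 "positive semi-definite")
})

test_that("spiked effects are recovered by regression and leave other SNPs null", {
    sc <- simSmallCohort(n = 5000, m = 60, seed = 11, nCausal = 10)
    betas <- c(LL = 0.020, UL = 0.187, SK = 0.169)
    target <- rownames(sc$panel)[30]
    spiked <- spikeEffect(sc$panel, sc$pheno, target, betas)
    gStd <- bonesite:::zstd(dosages(sc$panel)[target, ])
    for (tr in names(betas)) {
        y <- residualizeStandardize(spiked, tr, "model0")
        ## spiked effects are on the standardized-dosage scale
        fit <- dosageRegression(y, gStd)
        expect_lt(abs(fit$beta - betas[[tr]]), 2.5 * fit$se)
    }
    ## zero spike is the identity
    expect_equal(spikeEffect(sc$panel, sc$pheno, target,
                             c(LL = 0, UL = 0, SK = 0, TBLH = 0)),
                 sc$pheno)
    ## an independent SNP stays null
    y <- residualizeStandardize(spiked, "UL", "model0")
    other <- dosageRegression(y, dosages(sc$panel)[5, ])
    expect_lt(abs(other$beta), 3 * other$se)
    expect_error(spikeEffect(sc$panel, sc$pheno, "nope", betas), "unknown")
})

test_that("HWE exact test matches the enumeration oracle", {
    expect_identical(hweExactTest(100, 0, 0), 1)
    expect_equal(hweExactTest(5, 10, 5), hweEnumOracle(5, 10, 5),
                 tolerance = 1e-12)
    ## extreme-heterozygosity configurations vs the HWE-proportioned one
    expect_equal(hweExactTest(0, 20, 0), hweEnumOracle(0, 20, 0),
                 tolerance = 1e-12)
    expect_equal(hweExactTest(10, 0, 10), hweEnumOracle(10, 0, 10),
                 tolerance = 1e-12)
    expect_gt(hweExactTest(5, 10, 5), hweExactTest(0, 20, 0))
    expect_gt(hweExactTest(5, 10, 5), hweExactTest(10, 0, 10))
    expect_error(hweExactTest(0, 0, 0), "at least one")
    expect_error(hweExactTest(-1, 2, 3), "nonnegative")
})

test_that("QC filter excludes by MAF, call rate and HWE and is idempotent", {
    ## hand-built panel: 5 SNPs with known defects
    set.seed(1)
    d <- rbind(
        ok = rbinom(200, 2, 0.3),
        lowmaf = c(1, rep(0, 199)),            # MAF = 0.0025
        miss = rbinom(200, 2, 0.3),
        hwe = c(rep(0, 100), rep(2, 100)),     # no heterozygotes
        ok2 = rbinom(200, 2, 0.4))
    d["miss", sample(200, 12)] <- NA           # 6% missing
    storage.mode(d) <- "double"
    rd <- S4Vectors::DataFrame(CHR = 1:5, POS = 1:5,
                               EA = "A", NEA = "G")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = d), rowData = rd)
    colnames(se) <- paste0("i", 1:200)
    panel <- methods::new("DosagePanel", se)
    qc <- qcFilter(panel)
    expect_setequal(rownames(qc$panel), c("ok", "ok2"))
    expect_true(any(grepl("MAF", qc$report$reason[
        qc$report$SNP_ID == "lowmaf"])))
    expect_true(any(grepl("call rate", qc$report$reason[
        qc$report$SNP_ID == "miss"])))
    expect_true(any(grepl("HWE", qc$report$reason[
        qc$report$SNP_ID == "hwe"])))
    ## constructed HWE failure has enumeration P below the threshold
    expect_lt(hweEnumOracle(100, 0, 100), 5e-7)
    ## idempotent
    qc2 <- qcFilter(qc$panel)
    expect_equal(nrow(qc2$report), 0)
    expect_identical(rownames(qc2$panel), rownames(qc$panel))
})
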