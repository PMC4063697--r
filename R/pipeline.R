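#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: the cohort specs (sharing
#' one SNP map), the trait architecture, optional spiked site-specific
#' effects, per-cohort ancestry-PC counts, covariate set, genomic-control
#' switch, significance thresholds, relatedness cutoff and the master seed
#' every stage seed derives from.
#'
#' @param cohorts list of [cohortSpec()] objects (>= 2 for meta-analysis).
#' @param arch a [traitArchitecture()]; default [defaultTraitArchitecture()]
#'   with \code{nCausal} capped at the panel size.
#' @param spikes optional list of \code{list(snpId =, beta = named vector)}
#'   applied to every cohort.
#' @param covariateSet \code{"model0"} or \code{"model1a"}.
#' @param nPcs integer vector of ancestry-PC counts, one per cohort
#'   (default: 0 for the first cohort, 20 for the others).
#' @param gc apply per-cohort genomic control before meta (default TRUE).
#' @param gwsAlpha genome-wide significance threshold (default 5e-8).
#' @param sitespecAlpha site-specificity significance threshold
#'   (default 5e-8).
#' @param relatednessCutoff GRM pruning cutoff before REML (default 0.025).
#' @param doGreml,doSitespec,doConditional stage switches.
#' @param seed master seed; all stage seeds derive from it.
#' @param outDir optional directory for TSV/JSON outputs.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(cohorts, arch = NULL, spikes = list(),
                           covariateSet = "model0", nPcs = NULL,
                           gc = TRUE, gwsAlpha = 5e-8,
                           sitespecAlpha = 5e-8,
                           relatednessCutoff = 0.025,
                           doGreml = TRUE, doSitespec = TRUE,
                           doConditional = FALSE,
                           seed = 1L, outDir = NULL) {
    if (length(cohorts) < 1) stop("at least one cohort spec required")
    m <- cohorts[[1]]$nSnps
    if (is.null(arch))
        arch <- defaultTraitArchitecture(nCausal = max(1L,
                                                       min(2000L, m %/% 2L)))
    if (is.null(nPcs))
        nPcs <- c(0L, rep(20L, length(cohorts) - 1L))
    if (gwsAlpha <= 0 || gwsAlpha >= 1 || sitespecAlpha <= 0 ||
        sitespecAlpha >= 1)
        stop("alphas must lie in (0, 1)")
    structure(list(cohorts = cohorts, arch = arch, spikes = spikes,
                   covariateSet = covariateSet, nPcs = nPcs, gc = gc,
                   gwsAlpha = gwsAlpha, sitespecAlpha = sitespecAlpha,
                   relatednessCutoff = relatednessCutoff,
                   doGreml = doGreml, doSitespec = doSitespec,
                   doConditional = doConditional,
                   seed = as.integer(seed), outDir = outDir),
              class = "PipelineConfig")
}

#' Run the full skeletal-site analysis pipeline on synthetic cohorts
#'
#' simulate -> QC -> per-cohort association (with genomic control) ->
#' inverse-variance meta-analysis -> site-specificity testing of
#' genome-wide significant SNPs -> optional conditional analysis ->
#' GRM/REML variance components on the first cohort. Every stage draws its
#' seed from the master seed, and a manifest records seeds, record counts,
#' inflation factors and drop reasons.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with elements \code{panels}, \code{phenotypes},
#'   \code{qcReports}, \code{assoc} (per trait per cohort), \code{lambda},
#'   \code{meta} (per trait), \code{gws}, \code{sitespec}, \code{greml},
#'   \code{manifest}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    nC <- length(config$cohorts)
    seeds <- deriveSeeds(config$seed, 2L * nC + 2L)
    traits <- config$arch$traitNames
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    ## --- simulate ----------------------------------------------------------
    map <- stage("simulate", snpMap(config$cohorts[[1]]$nSnps,
                                    config$cohorts[[1]]$mafRange,
                                    seed = seeds[1]))
    panels <- vector("list", nC)
    phenos <- vector("list", nC)
    for (i in seq_len(nC)) {
        sp <- config$cohorts[[i]]
        sp$seed <- seeds[1L + i]
        panels[[i]] <- stage("simulate", simulateGenotypes(sp, map = map))
        phenos[[i]] <- stage("simulate", simulatePhenotypes(
            panels[[i]], config$arch, seed = seeds[1L + nC + i]))
        for (spk in config$spikes)
            phenos[[i]] <- stage("simulate", spikeEffect(
                panels[[i]], phenos[[i]], spk$snpId, spk$beta))
    }
    names(panels) <- names(phenos) <-
        vapply(config$cohorts, `[[`, "", "cohortId")

    ## --- QC ----------------------------------------------------------------
    qcReports <- vector("list", nC)
    for (i in seq_len(nC)) {
        qc <- stage("qc", qcFilter(panels[[i]]))
        panels[[i]] <- qc$panel
        qcReports[[i]] <- qc$report
    }

    ## --- association + GC --------------------------------------------------
    assoc <- list()
    lambda <- matrix(NA_real_, nC, length(traits),
                     dimnames = list(names(panels), traits))
    for (i in seq_len(nC)) for (tr in traits) {
        rec <- stage("assoc", assocScan(panels[[i]], phenos[[i]], tr,
                                        covariateSet = config$covariateSet,
                                        nPcs = config$nPcs[i],
                                        gc = config$gc))
        lambda[i, tr] <- attr(rec, "lambdaGC")
        assoc[[paste(names(panels)[i], tr, sep = ".")]] <- rec
    }

    ## --- meta-analysis ------------------------------------------------------
    meta <- list()
    gws <- list()
    if (nC >= 2) {
        for (tr in traits) {
            recs <- lapply(seq_len(nC), function(i)
                assoc[[paste(names(panels)[i], tr, sep = ".")]])
            mm <- stage("meta", metaAnalyze(recs, gcInput = FALSE,
                                            alpha = config$gwsAlpha))
            meta[[tr]] <- mm
            gws[[tr]] <- mm$MarkerName[mm$GWS]
        }
    }

    ## --- site specificity ---------------------------------------------------
    sitespec <- list()
    if (config$doSitespec && nC >= 1) {
        candidates <- unique(unlist(gws))
        if (!length(candidates) && length(config$spikes))
            candidates <- vapply(config$spikes, `[[`, "", "snpId")
        sites <- intersect(c("LL", "UL", "SK"), traits)
        for (sn in candidates) {
            cd <- list()
            for (i in seq_len(nC)) {
                if (!sn %in% rownames(panels[[i]])) next
                Y <- vapply(sites, function(tr)
                    residualizeStandardize(phenos[[i]], tr,
                                           config$covariateSet),
                    numeric(nrow(phenos[[i]])))
                cd[[names(panels)[i]]] <-
                    list(Y = Y, g = dosages(panels[[i]])[sn, ])
            }
            if (length(cd))
                sitespec[[sn]] <- stage("sitespec", siteSpecificityTest(
                    cd, snpId = sn, alpha = config$sitespecAlpha))
        }
    }

    ## --- conditional analysis ----------------------------------------------
    conditional <- NULL
    if (config$doConditional && length(gws)) {
        conditional <- list()
        for (tr in names(gws)) {
            hits <- gws[[tr]]
            if (length(hits) < 2) next
            ## condition every secondary hit on the trait's top SNP
            top <- meta[[tr]]$MarkerName[which.min(meta[[tr]]$P)]
            for (sn in setdiff(hits, top)) {
                rows <- lapply(seq_len(nC), function(i) {
                    y <- residualizeStandardize(phenos[[i]], tr,
                                                config$covariateSet)
                    g <- dosages(panels[[i]])[sn, ]
                    gcnd <- matrix(dosages(panels[[i]])[top, ], ncol = 1,
                                   dimnames = list(NULL, top))
                    stage("conditional",
                          conditionalRegression(y, g, gcnd))
                })
                conditional[[paste(tr, sn, sep = ".")]] <-
                    stage("conditional", conditionalMeta(do.call(rbind,
                                                                 rows)))
            }
        }
    }

    ## --- GREML --------------------------------------------------------------
    greml <- NULL
    if (config$doGreml) {
        greml <- stage("greml", {
            grm <- computeGrm(panels[[1]])
            keep <- pruneRelated(grm, config$relatednessCutoff)
            ki <- match(keep, grmIds(grm))
            grmK <- methods::new("Grm", k = grmMatrix(grm)[ki, ki],
                                 ids = keep, mSnps = grm@mSnps)
            es <- grmEigenDecomp(grmK)
            ph1 <- phenos[[1]][match(keep, phenos[[1]]$IID), , drop = FALSE]
            uni <- lapply(setNames(traits, traits), function(tr)
                remlUnivariate(residualizeStandardize(ph1, tr,
                                                      config$covariateSet),
                               es))
            biv <- NULL
            if (all(c("LL", "UL") %in% traits)) {
                Y <- cbind(LL = residualizeStandardize(ph1, "LL",
                                                       config$covariateSet),
                           UL = residualizeStandardize(ph1, "UL",
                                                       config$covariateSet))
                biv <- remlBivariate(Y, es)
            }
            list(grm = grmK, retained = keep, univariate = uni,
                 bivariate = biv)
        })
    }

    ## --- manifest ------------------------------------------------------------
    manifest <- list(
        masterSeed = config$seed,
        stageSeeds = as.list(setNames(seeds, c(
            "map", paste0("genotypes.", names(panels)),
            paste0("phenotypes.", names(panels)), "unused"))),
        cohorts = lapply(config$cohorts, function(s)
            s[c("cohortId", "nIndividuals", "nSnps")]),
        qcExcluded = vapply(qcReports, nrow, 0L),
        lambdaGC = round(lambda, 6),
        metaRecords = vapply(meta, nrow, 0L),
        gwsCount = vapply(gws, length, 0L),
        gwsSnps = gws,
        sitespecSignificant = vapply(sitespec, function(x)
            x@significant, TRUE),
        grmlRetained = if (!is.null(greml)) length(greml$retained) else NA)
    if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        for (tr in names(meta))
            writeSummaryStats(meta[[tr]],
                              file.path(config$outDir,
                                        paste0("meta_", tr, ".tsv")))
        jsonlite::write_json(manifest,
                             file.path(config$outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(list(panels = panels, phenotypes = phenos,
                   qcReports = qcReports, assoc = assoc, lambda = lambda,
                   meta = meta, gws = gws, sitespec = sitespec,
                   conditional = conditional, greml = greml,
                   manifest = manifest))
}
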