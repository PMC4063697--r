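## Plain-text readers/writers: dosage panels, phenotype tables,
## METAL-dialect summary statistics and the text GRM format.

#' Write / read a dosage panel
#'
#' Dosage file: TSV, one row per SNP with columns SNP_ID, CHR, POS, EA,
#' NEA followed by one dosage per individual (in [0, 2], NA = missing).
#' A companion \code{<path>.info} TSV carries SNP_ID, EAF and
#' imputation_quality. Numeric values round-trip at 15 significant
#' digits.
#'
#' @param panel a \linkS4class{DosagePanel}.
#' @param path dosage file path (the info file gets \code{.info} added).
#' @param cohort cohort label to attach on read.
#' @return \code{readDosage} returns a \linkS4class{DosagePanel};
#'   \code{writeDosage} returns \code{path} invisibly.
#' @export
writeDosage <- function(panel, path) {
    stopifnot(methods::is(panel, "DosagePanel"))
    d <- dosages(panel)
    info <- snpInfo(panel)
    tab <- data.frame(SNP_ID = rownames(d), CHR = info$CHR, POS = info$POS,
                      EA = info$EA, NEA = info$NEA,
                      format(d, digits = 15, trim = TRUE, scientific = FALSE),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(tab)[-(1:5)] <- colnames(d)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    eaf <- rowMeans(d, na.rm = TRUE) / 2
    writeLines(c("SNP_ID\tEAF\timputation_quality",
                 sprintf("%s\t%.15g\t1", rownames(d), eaf)),
               paste0(path, ".info"))
    invisible(path)
}

#' @rdname writeDosage
#' @export
readDosage <- function(path, cohort = NA_character_) {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("SNP_ID", "CHR", "POS", "EA", "NEA")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("dosage file missing mandatory column(s): ",
             paste(miss, collapse = ", "))
    d <- as.matrix(tab[, -(1:5), drop = FALSE])
    rownames(d) <- tab$SNP_ID
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = d),
        rowData = S4Vectors::DataFrame(CHR = tab$CHR, POS = tab$POS,
                                       EA = tab$EA, NEA = tab$NEA),
        colData = S4Vectors::DataFrame(IID = colnames(d),
                                       row.names = colnames(d)))
    S4Vectors::metadata(se)$cohort <- cohort
    methods::new("DosagePanel", se)
}

#' Write / read METAL-dialect summary statistics
#'
#' Mandatory columns: MarkerName, Allele1, Allele2, Freq1, Effect, StdErr,
#' P, N; any further columns are preserved. Values round-trip losslessly at
#' 15 significant digits (a P of 1.47e-37 survives exactly).
#'
#' @param records association/meta record data.frame.
#' @param path TSV path.
#' @return \code{readSummaryStats} returns the records;
#'   \code{writeSummaryStats} returns \code{path} invisibly.
#' @export
writeSummaryStats <- function(records, path) {
    out <- records
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], function(x) format(x, digits = 15,
                                                    trim = TRUE))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

SUMSTAT_COLS <- c("MarkerName", "Allele1", "Allele2", "Freq1", "Effect",
                  "StdErr", "P", "N")

#' @rdname writeSummaryStats
#' @export
readSummaryStats <- function(path) {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    miss <- setdiff(SUMSTAT_COLS, colnames(tab))
    if (length(miss))
        stop("summary-statistics file missing mandatory column(s): ",
             paste(miss, collapse = ", "))
    tab
}

#' Write / read a phenotype table
#'
#' TSV with header IID, AGE, SEX, WEIGHT, HEIGHT and one column per trait.
#'
#' @param phenotypes phenotype data.frame.
#' @param path TSV path.
#' @return \code{readPhenotypes} returns the data.frame.
#' @export
writePhenotypes <- function(phenotypes, path) {
    out <- phenotypes
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], function(x) format(x, digits = 15,
                                                    trim = TRUE))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"IID" %in% colnames(tab))
        stop("phenotype file missing mandatory column: IID")
    tab
}

#' Write / read a GRM in text triples format
#'
#' Gzip TSV of lower-triangle triples (i, j, m_snps, value) with a
#' companion \code{.id} file of one individual id per line (compatible
#' with the GCTA text-GRM layout).
#'
#' @param grm a \linkS4class{Grm}.
#' @param path output path (\code{.grm.gz} recommended); the id file gets
#'   \code{.id} appended to the stem.
#' @return \code{readGrm} returns a \linkS4class{Grm}.
#' @export
writeGrm <- function(grm, path) {
    A <- grmMatrix(grm)
    n <- nrow(A)
    idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    con <- gzfile(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d\t%d\t%d\t%.15g", idx[, 1], idx[, 2],
                       grm@mSnps, A[idx]), con)
    writeLines(grmIds(grm), sub("\\.grm\\.gz$|\\.gz$", "",
                                path) |> paste0(".id"))
    invisible(path)
}

#' @rdname writeGrm
#' @export
readGrm <- function(path) {
    tab <- read.delim(gzfile(path), header = FALSE,
                      col.names = c("i", "j", "m", "a"))
    ids <- readLines(sub("\\.grm\\.gz$|\\.gz$", "", path) |> paste0(".id"))
    n <- max(tab$i)
    A <- matrix(0, n, n)
    A[cbind(tab$i, tab$j)] <- tab$a
    A[cbind(tab$j, tab$i)] <- tab$a
    methods::new("Grm", k = A, ids = ids, mSnps = as.integer(tab$m[1]))
}

#' Published two-cohort BMD summary-statistic fixtures
#'
#' \code{gwsCohortStats()} returns the genome-wide significant SNPs of a
#' published paediatric total-body DXA BMD meta-analysis of two cohorts
#' (n = 5,330/5,299 and 4,086), with per-cohort and pooled effect-allele
#' frequency, effect (SD per allele), SE and P plus the printed I-squared
#' and heterogeneity P per trait. \code{siteSpecChiStats()} returns the
#' published per-site effect comparison table: per-site beta, 95% CI and P
#' together with the Fisher combination statistic (Chi, 4 df across two
#' cohorts) and its P.
#'
#' @return data.frame of the packaged table.
#' @export
gwsCohortStats <- function() {
    read.delim(system.file("extdata", "bmd_gws_cohort_stats.tsv",
                           package = "bonesite"),
               stringsAsFactors = FALSE)
}

#' @rdname gwsCohortStats
#' @export
siteSpecChiStats <- function() {
    read.delim(system.file("extdata", "bmd_sitespec_chi.tsv",
                           package = "bonesite"),
               stringsAsFactors = FALSE)
}
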