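#' Accessors for bonesite classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of the matching class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setMethod("dosages", "DosagePanel", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname accessors
#' @export
setMethod("snpInfo", "DosagePanel", function(x) {
    df <- as.data.frame(SummarizedExperiment::rowData(x))
    df <- cbind(SNP_ID = rownames(x), df)
    rownames(df) <- NULL
    df
})

#' @rdname accessors
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))

#' @rdname accessors
#' @export
setMethod("cohortId", "DosagePanel", function(x)
    S4Vectors::metadata(x)$cohort)

#' @rdname accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname accessors
#' @export
setMethod("grmMatrix", "Grm", function(x) x@k)

#' @rdname accessors
#' @export
setGeneric("grmIds", function(x) standardGeneric("grmIds"))

#' @rdname accessors
#' @export
setMethod("grmIds", "Grm", function(x) x@ids)

#' @rdname accessors
#' @export
setGeneric("vg", function(x) standardGeneric("vg"))

#' @rdname accessors
#' @export
setMethod("vg", "VarCompEstimate", function(x) x@vg)

#' @rdname accessors
#' @export
setGeneric("rg", function(x) standardGeneric("rg"))

#' @rdname accessors
#' @export
setMethod("rg", "BivarCompEstimate", function(x) x@rg)

#' @rdname accessors
#' @export
setGeneric("re", function(x) standardGeneric("re"))

#' @rdname accessors
#' @export
setMethod("re", "BivarCompEstimate", function(x) x@re)

#' @rdname accessors
#' @export
setGeneric("siteBetas", function(x) standardGeneric("siteBetas"))

#' @rdname accessors
#' @export
setMethod("siteBetas", "MvnSiteFit", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("fisherP", function(x) standardGeneric("fisherP"))

#' @rdname accessors
#' @export
setMethod("fisherP", "SiteSpecResult", function(x) x@fisherP)

#' @rdname accessors
#' @export
setMethod("logLik", "MvnSiteFit", function(object, ...) object@loglik)

#' @rdname accessors
#' @export
setMethod("logLik", "VarCompEstimate", function(object, ...) object@loglik)

#' @rdname accessors
#' @export
setMethod("logLik", "BivarCompEstimate", function(object, ...) object@loglik)
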