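#' Abundance mode of a container
#'
#' @param x an [AsvExperiment-class].
#' @return `"counts"` or `"relative"`.
#' @export
setGeneric("abundanceMode", function(x) standardGeneric("abundanceMode"))

#' @rdname abundanceMode
#' @export
setMethod("abundanceMode", "AsvExperiment", function(x) x@abundanceMode)

#' Convert counts to per-sample relative abundances
#'
#' Divides every sample column by its sum. All-zero columns are preserved as
#' zero and their ids recorded in `metadata(x)$zero_samples`. Idempotent on
#' relative-mode input.
#'
#' @param x an [AsvExperiment-class].
#' @return an [AsvExperiment-class] in `"relative"` mode.
#' @examples
#' m <- matrix(c(2, 3, 5), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
#' sd <- data.frame(sample_id = "s1", compartment = "water", depth_m = 5,
#'                  date_start = as.Date("2015-06-01"))
#' ae <- AsvExperiment(m, c(a = "AA", b = "CC", c = "GG"), sd)
#' SummarizedExperiment::assay(relativeAbundance(ae))[, 1]
#' @export
setGeneric("relativeAbundance", function(x) standardGeneric("relativeAbundance"))

#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "AsvExperiment", function(x) {
    if (identical(x@abundanceMode, "relative"))
        return(x)
    a <- SummarizedExperiment::assay(x)
    cs <- colSums(a)
    zero <- cs == 0
    if (any(zero))
        warning("all-zero sample column(s) left as zero: ",
                paste(colnames(a)[zero], collapse = ", "))
    scale <- ifelse(zero, 1, cs)
    SummarizedExperiment::assay(x) <- sweep(a, 2, scale, "/")
    x@abundanceMode <- "relative"
    metadata(x)$zero_samples <- colnames(a)[zero]
    methods::validObject(x)
    x
})

#' ASV sequences of a container
#'
#' @param x an [AsvExperiment-class].
#' @return a named [Biostrings::DNAStringSet].
#' @export
setGeneric("asvSequences", function(x) standardGeneric("asvSequences"))

#' @rdname asvSequences
#' @export
setMethod("asvSequences", "AsvExperiment", function(x) {
    s <- as.character(SummarizedExperiment::rowData(x)$dna_sequence)
    names(s) <- rownames(x)
    Biostrings::DNAStringSet(s)
})

#' SASV ids of a SasvSet
#'
#' Returns the canonical (water-side) ids of the shared set, sorted and
#' deduplicated.
#'
#' @param x a [SasvSet-class].
#' @return character vector.
#' @export
setGeneric("sasvIds", function(x) standardGeneric("sasvIds"))

#' @rdname sasvIds
#' @export
setMethod("sasvIds", "SasvSet", function(x) sort(unique(x@waterIds)))

#' Serialize a pipeline product to disk
#'
#' Tables ([data.frame]s, e.g. depth profiles, zone assignments, enrichment
#' results) are written as TSV with a fixed documented column order; fit
#' objects ([PowerLawFit-class]) as JSON. Use [readDepthProfile()] /
#' [readPowerLawFit()] to read them back.
#'
#' @param obj object to write.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
setGeneric("writeResults", function(obj, path) standardGeneric("writeResults"))

## show methods ---------------------------------------------------------------

setMethod("show", "AsvExperiment", function(object) {
    methods::callNextMethod()
    cat("abundanceMode:", object@abundanceMode, "\n")
    cmp <- table(SummarizedExperiment::colData(object)$compartment)
    cat("compartments:",
        paste(sprintf("%s (%d)", names(cmp), cmp), collapse = ", "), "\n")
})

setMethod("show", "MonthlyClimatology", function(object) {
    e <- object@entries
    cat(sprintf(
        "MonthlyClimatology: %d ASVs, %d (depth, month) entries\n",
        nrow(object@abund), nrow(e)))
    cat(sprintf("  depths: %s m\n",
                paste(sort(unique(e$depth_m)), collapse = ", ")))
    cat(sprintf("  months: %s (%d interpolated entries)\n",
                paste(sort(unique(e$month)), collapse = ", "),
                sum(e$interpolated)))
})

setMethod("show", "SasvSet", function(object) {
    cat(sprintf(
        "SasvSet: trap sample %s vs water %g m (month %d): %d shared ASVs\n",
        object@trapSampleId, object@waterDepth, object@month,
        length(unique(object@waterIds))))
})

setMethod("show", "PowerLawFit", function(object) {
    sref <- if (identical(object@scale, "fraction"))
        100 * object@sRef else object@sRef
    cat(sprintf("PowerLawFit: S_Z = S_%g * (Z/%g)^b\n",
                object@zRef, object@zRef))
    cat(sprintf("  S_%g = %.4g%%, b = %.4g (2-sigma CI %.4g..%.4g)\n",
                object@zRef, sref, object@b, object@ciB[1], object@ciB[2]))
    cat(sprintf("  R2 = %s, p = %.3g, n = %d, window %g-%g m\n",
                ifelse(is.na(object@r2), "undefined",
                       sprintf("%.4g", object@r2)),
                object@pValue, object@nPoints,
                object@depthWindow[1], object@depthWindow[2]))
    if (nzchar(object@note)) cat("  note:", object@note, "\n")
})
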