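## Readers and writers for the plain-text formats the pipeline consumes:
## ASV x sample count tables (TSV/CSV, delimiter autodetected), FASTA
## sequences, sample metadata CSV and particulate flux CSV.

.sniffSep <- function(path) {
    header <- readLines(path, n = 1L)
    if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Load an ASV dataset from counts + FASTA + metadata files
#'
#' Reads an ASV x sample count table (rows keyed by ASV id, columns by
#' sample id; tab- or comma-delimited, autodetected), a FASTA file of ASV
#' sequences (id = first whitespace token of the header) and a CSV of sample
#' metadata (required columns `sample_id`, `compartment`, `depth_m`,
#' `date_start`; optional `date_end`, `replicate`). FASTA records not
#' referenced by the count table are dropped with a warning; a count-table
#' ASV without a sequence, or a sample without metadata, is an error naming
#' the offending id.
#'
#' @param countsPath,fastaPath,metadataPath file paths.
#' @return an [AsvExperiment-class] in `"counts"` mode.
#' @seealso [exportAsvDataset()] for the inverse.
#' @export
readAsvDataset <- function(countsPath, fastaPath, metadataPath) {
    sep <- .sniffSep(countsPath)
    counts <- utils::read.table(countsPath, header = TRUE, sep = sep,
                                row.names = 1, check.names = FALSE,
                                stringsAsFactors = FALSE,
                                comment.char = "")
    for (j in seq_along(counts)) {
        if (!is.numeric(counts[[j]])) {
            bad <- which(is.na(suppressWarnings(as.numeric(counts[[j]]))))[1]
            stop(sprintf(
                "non-numeric count at row \"%s\", column \"%s\": \"%s\"",
                rownames(counts)[bad], colnames(counts)[j], counts[bad, j]))
        }
    }
    counts <- as.matrix(counts)

    seqs <- Biostrings::readDNAStringSet(fastaPath)
    headers <- names(seqs)
    names(seqs) <- sub("\\s.*$", "", headers)
    ## optional taxon label carried as the FASTA description
    desc <- trimws(sub("^\\S+\\s*", "", headers))
    taxonomy <- stats::setNames(ifelse(nzchar(desc), desc, NA_character_),
                                names(seqs))
    seqs <- normalizeDnaSequences(seqs)
    extra <- setdiff(names(seqs), rownames(counts))
    if (length(extra)) {
        warning(length(extra), " unreferenced FASTA record(s) dropped: ",
                paste(utils::head(extra, 5), collapse = ", "),
                if (length(extra) > 5) ", ..." else "")
        seqs <- seqs[setdiff(names(seqs), extra)]
    }
    missing_seq <- setdiff(rownames(counts), names(seqs))
    if (length(missing_seq))
        stop("count table ASV(s) missing from FASTA: ",
             paste(missing_seq, collapse = ", "))

    md <- utils::read.csv(metadataPath, stringsAsFactors = FALSE)
    need <- c("sample_id", "compartment", "depth_m", "date_start")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("metadata lacks required column(s): ",
             paste(miss, collapse = ", "))
    missing_md <- setdiff(colnames(counts), md$sample_id)
    if (length(missing_md))
        stop("count table sample(s) missing from metadata: ",
             paste(missing_md, collapse = ", "))
    if ("taxon" %in% colnames(md)) md$taxon <- NULL  # sample table only
    if (all(is.na(taxonomy))) taxonomy <- NULL
    AsvExperiment(counts, seqs, md, mode = "counts",
                  taxonomy = taxonomy)
}

#' Write an ASV dataset as counts TSV + FASTA + metadata CSV
#'
#' The inverse of [readAsvDataset()]; numeric values are written with 17
#' significant digits so a load/write/load round trip preserves them to
#' better than 1e-12.
#'
#' @param x an [AsvExperiment-class].
#' @param countsPath,fastaPath,metadataPath destination paths.
#' @return invisibly, the three paths.
#' @export
exportAsvDataset <- function(x, countsPath, fastaPath, metadataPath) {
    a <- SummarizedExperiment::assay(x)
    tab <- cbind(asv_id = rownames(a),
                 as.data.frame(formatC(a, format = "g", digits = 17),
                               check.names = FALSE))
    utils::write.table(tab, countsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    seqsOut <- asvSequences(x)
    rd <- SummarizedExperiment::rowData(x)
    if ("taxon" %in% colnames(rd)) {
        tax <- as.character(rd$taxon)
        lab <- ifelse(is.na(tax) | !nzchar(tax), names(seqsOut),
                      paste(names(seqsOut), tax))
        names(seqsOut) <- lab
    }
    Biostrings::writeXStringSet(seqsOut, fastaPath)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd <- cbind(sample_id = rownames(cd),
                cd[, setdiff(colnames(cd), "sample_id"), drop = FALSE])
    utils::write.csv(cd, metadataPath, row.names = FALSE, quote = FALSE)
    invisible(c(countsPath, fastaPath, metadataPath))
}

#' Read a particulate flux table
#'
#' CSV with columns `interval_start`, `interval_end`, `pc_flux`, `pn_flux`
#' and (optionally) the annual reference means `pc_ref_mean`, `pn_ref_mean`
#' used by [flagSep()]; reference means may instead be passed to `flagSep`
#' directly.
#'
#' @param path CSV file path.
#' @return data.frame with Date interval columns.
#' @export
readFluxTable <- function(path) {
    fx <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("interval_start", "interval_end", "pc_flux", "pn_flux")
    miss <- setdiff(need, colnames(fx))
    if (length(miss))
        stop("flux table lacks required column(s): ",
             paste(miss, collapse = ", "))
    fx$interval_start <- as.Date(fx$interval_start)
    fx$interval_end <- as.Date(fx$interval_end)
    if (any(fx$interval_end < fx$interval_start))
        stop("flux interval_end precedes interval_start")
    fx
}

## writeResults methods -------------------------------------------------------

#' @describeIn writeResults tables go to TSV with 17 significant digits.
#' @export
setMethod("writeResults", "data.frame", function(obj, path) {
    out <- obj
    for (j in seq_along(out))
        if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
            out[[j]] <- formatC(out[[j]], format = "g", digits = 17)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
})

#' @describeIn writeResults fit objects go to JSON (s_ref in percent).
#' @export
setMethod("writeResults", "PowerLawFit", function(obj, path) {
    sref <- if (identical(obj@scale, "fraction")) 100 * obj@sRef else obj@sRef
    jsonlite::write_json(list(
        z_ref = obj@zRef, s_ref = sref, s_ref_scale = "percent",
        b = obj@b, se_b = obj@se, r2 = obj@r2, p_value = obj@pValue,
        ci_b = obj@ciB, n_points = obj@nPoints,
        depth_window = obj@depthWindow,
        p_value_method = "t statistic of b from the NLS covariance, df = n - 2",
        note = obj@note),
        path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    invisible(path)
})

#' Read back a depth profile (or any TSV written by writeResults)
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readDepthProfile <- function(path)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)

#' Read back a PowerLawFit written by writeResults
#'
#' @param path JSON path.
#' @return a [PowerLawFit-class] (sRef restored to fraction scale).
#' @export
readPowerLawFit <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    asNum <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    methods::new("PowerLawFit",
        zRef = asNum(j$z_ref), sRef = asNum(j$s_ref) / 100,
        b = asNum(j$b), se = asNum(j$se_b), r2 = asNum(j$r2),
        pValue = asNum(j$p_value), ciB = as.numeric(j$ci_b),
        nPoints = as.integer(j$n_points),
        depthWindow = as.numeric(j$depth_window),
        scale = "fraction",
        note = if (is.null(j$note)) "" else j$note)
}
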