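#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
NULL

## ---------------------------------------------------------------------------
## AsvExperiment
## ---------------------------------------------------------------------------

#' ASV abundance container
#'
#' An `AsvExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' and holds one ASV x sample abundance assay together with per-ASV sequences
#' and taxonomy (`rowData`) and per-sample metadata (`colData`). The
#' `abundanceMode` slot records whether the assay contains raw read counts
#' (`"counts"`) or per-sample relative abundances (`"relative"`, every
#' non-empty column summing to one).
#'
#' Required `colData` columns are `compartment` (`"water"` or `"trap"`),
#' `depth_m` (positive, metres), `date_start` (and `date_end` for trap
#' collection intervals), and `month` (1-12; for a trap sample the month of
#' the interval midpoint). `rowData` must contain `dna_sequence`
#' (A/C/G/T/N strings) and may contain `taxon`.
#'
#' @slot abundanceMode character, `"counts"` or `"relative"`.
#' @seealso [AsvExperiment()], [relativeAbundance()], [readAsvDataset()]
#' @export
setClass("AsvExperiment",
    contains = "SummarizedExperiment",
    slots = c(abundanceMode = "character"))

.validAsvExperiment <- function(object) {
    msg <- character(0)
    mode <- object@abundanceMode
    if (length(mode) != 1L || !mode %in% c("counts", "relative"))
        msg <- c(msg, "abundanceMode must be \"counts\" or \"relative\"")
    a <- SummarizedExperiment::assay(object)
    if (any(a < 0))
        msg <- c(msg, "abundance values must be nonnegative")
    rd <- SummarizedExperiment::rowData(object)
    if (!"dna_sequence" %in% colnames(rd)) {
        msg <- c(msg, "rowData must contain a dna_sequence column")
    } else {
        seqs <- as.character(rd$dna_sequence)
        if (any(is.na(seqs)) || any(nchar(seqs) == 0L))
            msg <- c(msg, "all dna_sequence entries must be non-empty")
        else if (any(grepl("[^ACGTN]", seqs)))
            msg <- c(msg, "dna_sequence alphabet must be within {A,C,G,T,N}")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("compartment", "depth_m", "month")
    miss <- setdiff(need, colnames(cd))
    if (length(miss)) {
        msg <- c(msg, paste0("colData lacks required column(s): ",
                             paste(miss, collapse = ", ")))
    } else {
        if (!all(cd$compartment %in% c("water", "trap")))
            msg <- c(msg, "compartment must be \"water\" or \"trap\"")
        if (!all(cd$depth_m > 0))
            msg <- c(msg, "depth_m must be positive")
        if (!all(cd$month %in% 1:12))
            msg <- c(msg, "month must be in 1..12")
    }
    if (identical(mode, "relative") && ncol(a)) {
        cs <- colSums(a)
        if (!all(abs(cs - 1) <= 1e-9 | cs == 0))
            msg <- c(msg, "relative-mode columns must sum to 1 (or be all zero)")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "asv ids (rownames) must be unique")
    if (length(msg)) msg else TRUE
}

setValidity("AsvExperiment", .validAsvExperiment)

#' Construct an AsvExperiment
#'
#' @param abund numeric matrix, ASVs x samples. Rownames are ASV ids,
#'   colnames sample ids.
#' @param sequences named character vector (or
#'   [Biostrings::DNAStringSet]) of ASV sequences covering every row of
#'   `abund`. Lowercase letters are uppercased and U is mapped to T.
#' @param sampleData data.frame of per-sample metadata with columns
#'   `compartment`, `depth_m`, `date_start` (and optionally `date_end`,
#'   `replicate`); one row per column of `abund` (matched by rownames or a
#'   `sample_id` column). A `month` column is derived if absent: the
#'   calendar month of `date_start` for water samples, of the interval
#'   midpoint for trap samples.
#' @param mode `"counts"` or `"relative"`.
#' @param taxonomy optional named character vector of taxon labels.
#' @return An [AsvExperiment-class] object.
#' @examples
#' m <- matrix(c(2, 3, 5, 1, 0, 9), nrow = 3,
#'             dimnames = list(c("a1", "a2", "a3"), c("s1", "s2")))
#' sd <- data.frame(sample_id = c("s1", "s2"), compartment = "water",
#'                  depth_m = 75, date_start = as.Date("2015-03-10"))
#' ae <- AsvExperiment(m, c(a1 = "ACGT", a2 = "GGTA", a3 = "TTAA"), sd)
#' abundanceMode(ae)
#' @export
AsvExperiment <- function(abund, sequences, sampleData, mode = "counts",
                          taxonomy = NULL) {
    abund <- as.matrix(abund)
    if (is.null(rownames(abund)) || is.null(colnames(abund)))
        stop("abundance matrix needs ASV rownames and sample colnames")
    sequences <- normalizeDnaSequences(sequences)
    missing_seq <- setdiff(rownames(abund), names(sequences))
    if (length(missing_seq))
        stop("no sequence provided for ASV(s): ",
             paste(missing_seq, collapse = ", "))
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% colnames(sampleData))
        rownames(sampleData) <- sampleData$sample_id
    missing_md <- setdiff(colnames(abund), rownames(sampleData))
    if (length(missing_md))
        stop("no metadata provided for sample(s): ",
             paste(missing_md, collapse = ", "))
    sampleData <- sampleData[colnames(abund), , drop = FALSE]
    for (dcol in intersect(c("date_start", "date_end"), colnames(sampleData)))
        sampleData[[dcol]] <- as.Date(sampleData[[dcol]])
    if (!"month" %in% colnames(sampleData))
        sampleData$month <- deriveSampleMonth(sampleData)
    sampleData$month <- as.integer(sampleData$month)
    if (!"n_reads" %in% colnames(sampleData))
        sampleData$n_reads <- if (identical(mode, "counts"))
            as.numeric(colSums(abund)) else NA_real_
    rd <- DataFrame(dna_sequence = unname(sequences[rownames(abund)]),
                    row.names = rownames(abund))
    if (!is.null(taxonomy))
        rd$taxon <- unname(taxonomy[rownames(abund)])
    se <- SummarizedExperiment(
        assays = S4Vectors::SimpleList(abund = abund),
        rowData = rd,
        colData = DataFrame(sampleData))
    new("AsvExperiment", se, abundanceMode = mode)
}

#' Calendar month of a sample
#'
#' Water samples take the month of `date_start`; trap samples take the month
#' of the midpoint of `[date_start, date_end]`, which generalizes pairing a
#' trap interval with the climatology month it mostly overlaps.
#'
#' @param sampleData data.frame with `compartment`, `date_start` and
#'   optionally `date_end`.
#' @return integer vector of months in 1..12.
#' @export
deriveSampleMonth <- function(sampleData) {
    start <- as.Date(sampleData$date_start)
    end <- if ("date_end" %in% colnames(sampleData))
        as.Date(sampleData$date_end) else start
    end[is.na(end)] <- start[is.na(end)]
    if (any(end < start, na.rm = TRUE))
        stop("interval_end precedes interval_start for some sample(s)")
    mid <- start + floor(as.numeric(end - start) / 2)
    as.integer(format(mid, "%m"))
}

#' Normalize DNA sequences to the A/C/G/T/N alphabet
#'
#' Uppercases and maps U to T.
#' @param sequences named character vector or DNAStringSet/RNAStringSet.
#' @return named uppercase character vector.
#' @export
normalizeDnaSequences <- function(sequences) {
    if (methods::is(sequences, "XStringSet"))
        sequences <- as.character(sequences)
    out <- chartr("u", "t", toupper(sequences))
    out <- chartr("U", "T", out)
    if (is.null(names(out)))
        stop("sequences must be named by ASV id")
    out
}

## ---------------------------------------------------------------------------
## MonthlyClimatology
## ---------------------------------------------------------------------------

#' Monthly water-column climatology
#'
#' Holds, for every (depth, calendar month) with water-column coverage, the
#' mean relative-abundance vector across years. Columns of `abund` are keyed
#' `"<depth>m.<month>"`; `entries` records depth, month, the number of years
#' averaged and whether the entry was interpolated from adjacent months.
#'
#' @slot abund numeric matrix, ASVs x (depth, month) entries.
#' @slot entries data.frame with columns `depth_m`, `month`, `n_years`,
#'   `interpolated`.
#' @seealso [monthlyClimatology()], [interpolateMissingMonths()]
#' @export
setClass("MonthlyClimatology",
    slots = c(abund = "matrix", entries = "data.frame"))

setValidity("MonthlyClimatology", function(object) {
    msg <- character(0)
    if (ncol(object@abund) != nrow(object@entries))
        msg <- c(msg, "one entries row is required per abundance column")
    need <- c("depth_m", "month", "n_years", "interpolated")
    if (!all(need %in% colnames(object@entries)))
        msg <- c(msg, paste0("entries must have columns ",
                             paste(need, collapse = ", ")))
    if (ncol(object@abund)) {
        cs <- colSums(object@abund)
        if (!all(abs(cs - 1) <= 1e-9 | cs == 0))
            msg <- c(msg, "climatology vectors must sum to 1 (or be empty)")
    }
    if (length(msg)) msg else TRUE
})

.climKey <- function(depth_m, month) sprintf("%gm.%02d", depth_m, month)

## ---------------------------------------------------------------------------
## SasvSet
## ---------------------------------------------------------------------------

#' Shared-ASV (SASV) set
#'
#' The ASVs shared between one trap sample and the water column at one
#' (depth, month) climatology entry, matched by exact (or N-wildcard)
#' sequence identity. Trap-side and water-side ids are kept as matched
#' pairs because the two compartments may use different ASV namespaces.
#'
#' @slot trapSampleId character scalar.
#' @slot waterDepth numeric scalar, metres.
#' @slot month integer scalar, 1-12.
#' @slot trapIds,waterIds parallel character vectors of matched ASV ids.
#' @seealso [identifySasvs()], [waterFraction()], [trapFraction()]
#' @export
setClass("SasvSet",
    slots = c(trapSampleId = "character", waterDepth = "numeric",
              month = "integer", trapIds = "character",
              waterIds = "character"))

setValidity("SasvSet", function(object) {
    if (length(object@trapIds) != length(object@waterIds))
        "trapIds and waterIds must be matched pairs of equal length"
    else TRUE
})

## ---------------------------------------------------------------------------
## PowerLawFit
## ---------------------------------------------------------------------------

#' Power-law depth-attenuation fit
#'
#' Result of fitting S_Z = S_ref * (Z / Z_ref)^b to a depth profile of SASV
#' relative abundances, after the Martin-curve description of particle flux
#' attenuation. `sRef` is stored on the scale recorded in `scale`
#' (`"fraction"` internally; printed and serialized as percent).
#'
#' @slot zRef reference depth, metres.
#' @slot sRef fitted reference abundance.
#' @slot b fitted dimensionless exponent.
#' @slot se standard error of `b` from the fit covariance.
#' @slot r2 coefficient of determination on the linear scale (`NA` when the
#'   profile has zero variance).
#' @slot pValue two-sided p-value for b = 0 (t statistic, df = n - 2).
#' @slot ciB length-2 numeric, b +/- 2 * se (95 percent, two-sigma).
#' @slot nPoints number of depths used.
#' @slot depthWindow length-2 numeric, depth window fitted.
#' @slot scale `"fraction"` or `"percent"`.
#' @slot note character, fit annotations (e.g. degenerate profiles).
#' @seealso [fitPowerLaw()], [refitReference()]
#' @export
setClass("PowerLawFit",
    slots = c(zRef = "numeric", sRef = "numeric", b = "numeric",
              se = "numeric", r2 = "numeric", pValue = "numeric",
              ciB = "numeric", nPoints = "integer",
              depthWindow = "numeric", scale = "character",
              note = "character"))

setValidity("PowerLawFit", function(object) {
    msg <- character(0)
    if (object@nPoints < 2L)
        msg <- c(msg, "a power-law fit needs at least 2 points")
    if (length(object@ciB) != 2L)
        msg <- c(msg, "ciB must have length 2")
    else if (!anyNA(object@ciB) &&
             (object@b < object@ciB[1] - 1e-12 ||
              object@b > object@ciB[2] + 1e-12))
        msg <- c(msg, "ciB must contain b")
    p <- object@pValue
    if (!is.na(p) && (p <= 0 || p > 1))
        msg <- c(msg, "pValue must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})
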