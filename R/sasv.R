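## SASV identification (exact-sequence matching of trap ASVs against the
## water-column climatology) and the two directions of SASV fraction:
## water-column fraction per origin depth, and trap fraction per origin depth.

.matchWithN <- function(query, subject) {
    ## N-wildcard sequence matching at equal length; returns index into
    ## subject for each query (first hit), NA if none. O(nq * ns), intended
    ## for the residual unmatched sets only.
    idx <- rep(NA_integer_, length(query))
    if (!length(query) || !length(subject)) return(idx)
    qs <- strsplit(query, "")
    ss <- strsplit(subject, "")
    for (i in seq_along(qs)) {
        q <- qs[[i]]
        for (j in seq_along(ss)) {
            s <- ss[[j]]
            if (length(q) != length(s)) next
            if (all(q == s | q == "N" | s == "N")) { idx[i] <- j; break }
        }
    }
    idx
}

#' Map trap ASVs onto water ASVs by sequence identity
#'
#' @param trapSequences,waterSequences named character vectors.
#' @param nWildcard also match sequences of equal length that differ only at
#'   positions where either carries an `N` (covers datasets without the
#'   fixed masked-base convention).
#' @return integer vector along `trapSequences`: index of the matching
#'   water ASV, `NA` if none.
#' @export
matchAsvSequences <- function(trapSequences, waterSequences,
                              nWildcard = FALSE) {
    t_up <- toupper(trapSequences)
    w_up <- toupper(waterSequences)
    idx <- match(t_up, w_up)
    if (nWildcard && anyNA(idx)) {
        un <- which(is.na(idx))
        idx[un] <- .matchWithN(t_up[un], w_up)
    }
    idx
}

#' Identify the SASVs of one trap sample at one water depth
#'
#' A SASV is an ASV with nonzero abundance in the trap sample whose
#' sequence is identical (string equality after uppercasing; optionally
#' N-wildcard) to a water-column ASV with nonzero climatology abundance at
#' the given (depth, month).
#'
#' @param trap an [AsvExperiment-class] of trap samples in relative mode.
#' @param trapSampleId column of `trap` to use.
#' @param clim a [MonthlyClimatology-class] of the water column.
#' @param depth_m,month climatology entry to compare against (an absent
#'   entry is an error); `month` defaults to the trap sample's own month.
#' @param waterSequences named character vector of water ASV sequences
#'   covering the climatology rows. If `NULL`, trap and water are assumed to
#'   share one ASV namespace and ids are matched directly.
#' @param nWildcard see [matchAsvSequences()].
#' @param minPresence presence floor: an ASV counts as present when its
#'   relative abundance is strictly greater than this (default 0).
#' @return a [SasvSet-class].
#' @export
identifySasvs <- function(trap, trapSampleId, clim, depth_m, month = NULL,
                          waterSequences = NULL, nWildcard = FALSE,
                          minPresence = 0) {
    if (!identical(abundanceMode(trap), "relative"))
        stop("identifySasvs expects the trap matrix in relative mode")
    if (!trapSampleId %in% colnames(trap))
        stop("unknown trap sample: ", trapSampleId)
    if (is.null(month))
        month <- SummarizedExperiment::colData(trap)[trapSampleId, "month"]
    cv <- climatologyAbundance(clim, depth_m, month)
    tv <- SummarizedExperiment::assay(trap)[, trapSampleId]
    trapPresent <- names(tv)[tv > minPresence]
    waterPresent <- names(cv)[cv > minPresence]
    if (is.null(waterSequences)) {
        shared <- intersect(trapPresent, waterPresent)
        trapIds <- shared
        waterIds <- shared
    } else {
        trapSeq <- as.character(
            SummarizedExperiment::rowData(trap)[trapPresent, "dna_sequence"])
        idx <- matchAsvSequences(trapSeq, waterSequences[waterPresent],
                                 nWildcard = nWildcard)
        hit <- !is.na(idx)
        trapIds <- trapPresent[hit]
        waterIds <- waterPresent[idx[hit]]
    }
    methods::new("SasvSet", trapSampleId = trapSampleId,
                 waterDepth = depth_m, month = as.integer(month),
                 trapIds = trapIds, waterIds = waterIds)
}

#' Water-column SASV fraction
#'
#' Summed climatology relative abundance, at the set's (depth, month), of
#' the water-side SASVs. Lies in [0, 1].
#'
#' @param sasv a [SasvSet-class].
#' @param clim the [MonthlyClimatology-class] the set was identified
#'   against.
#' @return numeric fraction.
#' @export
waterFraction <- function(sasv, clim) {
    cv <- climatologyAbundance(clim, sasv@waterDepth, sasv@month)
    sum(cv[unique(sasv@waterIds)])
}

#' Trap SASV fraction by origin depth
#'
#' Summed relative abundance, in the trap sample, of the trap-side SASVs.
#' Across origin depths these fractions can sum to more than one: an ASV
#' found in the water column at several depths contributes its full trap
#' abundance at each of them.
#'
#' @param sasv a [SasvSet-class].
#' @param trap the trap [AsvExperiment-class] (relative mode).
#' @return numeric fraction.
#' @export
trapFraction <- function(sasv, trap) {
    tv <- SummarizedExperiment::assay(trap)[, sasv@trapSampleId]
    sum(tv[unique(sasv@trapIds)])
}

#' SASV fractions for every (trap sample, water depth) pair
#'
#' The pipeline workhorse: identifies the SASV set of every trap sample
#' against the climatology at every requested depth (each sample paired
#' with its own month) and tabulates both fraction statistics.
#'
#' @inheritParams identifySasvs
#' @param depths water depths to profile; default, all climatology depths.
#' @param sampleIds trap samples to use; default, all.
#' @param returnSets also return the [SasvSet-class] objects.
#' @return data.frame with columns `sample_id`, `depth_m`, `month`,
#'   `n_sasvs`, `water_fraction`, `trap_fraction`; if `returnSets`, a list
#'   with elements `table` and `sets`.
#' @export
sasvFractionTable <- function(trap, clim, waterSequences = NULL,
                              depths = NULL, sampleIds = NULL,
                              nWildcard = FALSE, minPresence = 0,
                              returnSets = FALSE) {
    if (!identical(abundanceMode(trap), "relative"))
        stop("sasvFractionTable expects the trap matrix in relative mode")
    if (is.null(depths)) depths <- climatologyDepths(clim)
    if (is.null(sampleIds)) sampleIds <- colnames(trap)
    cd <- SummarizedExperiment::colData(trap)
    ta <- SummarizedExperiment::assay(trap)
    ## global trap->water id correspondence, computed once
    if (is.null(waterSequences)) {
        wIdx <- match(rownames(trap), rownames(clim@abund))
    } else {
        trapSeq <- as.character(
            SummarizedExperiment::rowData(trap)$dna_sequence)
        wSeqs <- waterSequences[rownames(clim@abund)]
        wIdx <- matchAsvSequences(trapSeq, wSeqs, nWildcard = nWildcard)
    }
    waterNames <- rownames(clim@abund)
    rows <- vector("list", length(sampleIds) * length(depths))
    sets <- if (returnSets) vector("list", length(rows)) else NULL
    r <- 0L
    for (s in sampleIds) {
        tv <- ta[, s]
        month <- cd[s, "month"]
        trapPos <- tv > minPresence & !is.na(wIdx)
        for (d in depths) {
            cv <- climatologyAbundance(clim, d, month)
            sel <- trapPos & cv[wIdx] > minPresence
            wIds <- unique(wIdx[sel])
            r <- r + 1L
            rows[[r]] <- data.frame(
                sample_id = s, depth_m = d, month = as.integer(month),
                n_sasvs = length(wIds),
                water_fraction = sum(cv[wIds]),
                trap_fraction = sum(tv[sel]))
            if (returnSets)
                sets[[r]] <- methods::new("SasvSet", trapSampleId = s,
                    waterDepth = d, month = as.integer(month),
                    trapIds = rownames(trap)[sel],
                    waterIds = waterNames[wIdx[sel]])
        }
    }
    tbl <- do.call(rbind, rows)
    rownames(tbl) <- NULL
    if (returnSets) list(table = tbl, sets = sets) else tbl
}

#' Summarize a fraction table into a depth profile
#'
#' Per depth: mean, sample standard deviation and n of the chosen fraction
#' statistic across trap collection intervals (or replicates). A singleton
#' depth gets sd = 0 by convention.
#'
#' @param tbl fraction table from [sasvFractionTable()] (or any data.frame
#'   with `depth_m` plus the value column).
#' @param value column to summarize, `"water_fraction"` (default) or
#'   `"trap_fraction"`.
#' @return data.frame with columns `depth_m`, `mean`, `sd`, `n`, sorted by
#'   depth.
#' @export
profileOverTime <- function(tbl, value = "water_fraction") {
    if (!value %in% colnames(tbl))
        stop("no column named ", value)
    parts <- split(tbl[[value]], tbl$depth_m)
    out <- data.frame(
        depth_m = as.numeric(names(parts)),
        mean = vapply(parts, mean, numeric(1)),
        sd = vapply(parts, function(v)
            if (length(v) == 1L) 0 else stats::sd(v), numeric(1)),
        n = lengths(parts), row.names = NULL)
    out[order(out$depth_m), , drop = FALSE]
}

#' SASV richness by origin depth
#'
#' Number of distinct water-side ASV ids in the union of SASV sets per
#' depth, across trap collection intervals.
#'
#' @param sets list of [SasvSet-class] objects (e.g. from
#'   [sasvFractionTable()] with `returnSets = TRUE`).
#' @return data.frame with columns `depth_m`, `richness`.
#' @export
sasvRichnessByDepth <- function(sets) {
    depths <- vapply(sets, function(s) s@waterDepth, numeric(1))
    out <- lapply(split(sets, depths), function(grp)
        length(unique(unlist(lapply(grp, function(s) s@waterIds)))))
    data.frame(depth_m = as.numeric(names(out)),
               richness = as.integer(unlist(out)), row.names = NULL)
}
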