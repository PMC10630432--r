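## Depth-zone ecotype classification: abundance filtering of SASV
## water-column profiles, detection of depth maxima, the bimodal-retention
## rules, and per-zone taxon composition.

#' The six default depth-zone bins
#'
#' Surface 5-75 m, DCM (deep chlorophyll maximum) 100-150 m, Lower Euphotic
#' 175-200 m, Upper Mesopelagic 225-500 m, Lower Mesopelagic 770-1000 m,
#' Bathypelagic 2000-4000 m.
#'
#' @return data.frame with columns `label`, `z_min`, `z_max`.
#' @export
depthZoneTable <- function() {
    data.frame(
        label = c("Surface", "DCM", "LowerEuphotic", "UpperMesopelagic",
                  "LowerMesopelagic", "Bathypelagic"),
        z_min = c(5, 100, 175, 225, 770, 2000),
        z_max = c(75, 150, 200, 500, 1000, 4000))
}

#' Map depths onto zones
#'
#' A depth inside a zone's bounds takes that zone; a depth falling between
#' bounds (possible only on custom grids) takes the zone whose bound
#' interval midpoint is nearest.
#'
#' @param depth_m numeric depths, metres.
#' @param zones zone table as from [depthZoneTable()].
#' @return character vector of zone labels.
#' @export
assignDepthZone <- function(depth_m, zones = depthZoneTable()) {
    mid <- (zones$z_min + zones$z_max) / 2
    vapply(depth_m, function(z) {
        inside <- which(z >= zones$z_min & z <= zones$z_max)
        if (length(inside) == 1L) return(zones$label[inside])
        if (length(inside) > 1L)
            stop(sprintf("depth %g m falls in overlapping zones", z))
        zones$label[which.min(abs(mid - z))]
    }, character(1))
}

#' Filter SASVs by their profile maximum
#'
#' Keeps SASVs whose time-averaged water-column profile reaches at least
#' `threshold` (default 0.001, i.e. 0.1 percent, inclusive) at some depth.
#'
#' @param profiles numeric matrix, SASVs x depths.
#' @param threshold inclusive relative-abundance floor on the profile max.
#' @return the retained rows of `profiles`.
#' @export
selectAbundant <- function(profiles, threshold = 0.001) {
    profiles[apply(profiles, 1, max) >= threshold, , drop = FALSE]
}

#' Find the depth maxima of a profile
#'
#' An interior peak is a value strictly greater than both neighbours; a
#' plateau of equal values flanked by smaller values counts once, at its
#' shallowest depth. Boundary depths count as peaks when strictly greater
#' than their single neighbour iff `edgePeaks` (default `TRUE`, so that
#' surface-maximal taxa are classifiable; set `FALSE` to reproduce
#' boundary-excluding peak finders). A constant profile has no peaks.
#'
#' @param values profile values, ordered shallow to deep (reordered by
#'   `depths` if not).
#' @param depths depths parallel to `values`; at least 3 required.
#' @param edgePeaks allow peaks at the first/last depth.
#' @return numeric vector of peak depths (possibly empty).
#' @examples
#' findDepthMaxima(c(1, 5, 2, 6, 1), c(75, 100, 125, 150, 175))
#' @export
findDepthMaxima <- function(values, depths, edgePeaks = TRUE) {
    if (length(values) != length(depths))
        stop("values and depths must be parallel")
    if (length(values) < 3L)
        stop("peak finding needs at least 3 depths")
    ord <- order(depths)
    values <- values[ord]; depths <- depths[ord]
    r <- rle(values)
    k <- length(r$values)
    if (k == 1L) return(numeric(0))
    starts <- cumsum(r$lengths) - r$lengths + 1L
    peaks <- numeric(0)
    for (i in seq_len(k)) {
        leftOk <- if (i == 1L) edgePeaks else r$values[i] > r$values[i - 1L]
        rightOk <- if (i == k) edgePeaks else r$values[i] > r$values[i + 1L]
        if (leftOk && rightOk)
            peaks <- c(peaks, depths[starts[i]])
    }
    peaks
}

#' Classify SASVs into depth zones from their profile maxima
#'
#' Single-peak SASVs are retained with the zone of their peak depth.
#' Bimodal SASVs are retained when (rule 1) exactly one of the two maxima
#' exceeds the depth-averaged water-column relative abundance (the
#' unweighted mean of the profile over all grid depths), taking that peak's
#' zone, or (rule 2) both maxima fall in a single zone; otherwise they are
#' excluded. SASVs with more than two peaks are excluded as multimodal, and
#' peakless profiles (possible with `edgePeaks = FALSE`) as `no_peak`.
#'
#' @param profiles numeric matrix, SASVs x depths (column names are depths
#'   unless `depths` is given), typically [timeAveragedProfiles()] output
#'   filtered by [selectAbundant()].
#' @param depths numeric depths for the columns.
#' @param zones zone table as from [depthZoneTable()].
#' @param edgePeaks see [findDepthMaxima()].
#' @return data.frame with columns `asv_id`, `n_peaks`, `peak_depths`
#'   (";"-joined), `depth_averaged_mean`, `retained`, `zone`, `reason`.
#' @export
classifyDepthZones <- function(profiles, depths = NULL,
                               zones = depthZoneTable(), edgePeaks = TRUE) {
    if (is.null(depths)) depths <- as.numeric(colnames(profiles))
    if (anyNA(depths))
        stop("depths must be supplied or encoded as column names")
    rows <- lapply(seq_len(nrow(profiles)), function(i) {
        v <- profiles[i, ]
        p <- findDepthMaxima(v, depths, edgePeaks = edgePeaks)
        dam <- mean(v)
        res <- data.frame(asv_id = rownames(profiles)[i],
                          n_peaks = length(p),
                          peak_depths = paste(p, collapse = ";"),
                          depth_averaged_mean = dam, retained = FALSE,
                          zone = NA_character_, reason = NA_character_)
        if (length(p) == 0L) {
            res$reason <- "no_peak"
        } else if (length(p) == 1L) {
            res$retained <- TRUE
            res$zone <- assignDepthZone(p, zones)
        } else if (length(p) == 2L) {
            pv <- v[match(p, depths)]
            above <- pv > dam
            pz <- assignDepthZone(p, zones)
            if (sum(above) == 1L) {           # rule 1
                res$retained <- TRUE
                res$zone <- pz[above]
            } else if (pz[1] == pz[2]) {      # rule 2
                res$retained <- TRUE
                res$zone <- pz[1]
            } else {
                res$reason <- "bimodal_unresolved"
            }
        } else {
            res$reason <- "multimodal"
        }
        res
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Bookkeeping counts of a zone classification
#'
#' @param assignments output of [classifyDepthZones()].
#' @return named integer vector: `n_abundant`, `n_single`, `n_bimodal`,
#'   `n_multimodal`, `n_no_peak`, `n_retained`, `n_excluded`, plus
#'   per-zone retained counts prefixed `zone_`.
#' @export
zoneCounts <- function(assignments) {
    zc <- table(assignments$zone[assignments$retained])
    out <- c(n_abundant = nrow(assignments),
             n_single = sum(assignments$n_peaks == 1L),
             n_bimodal = sum(assignments$n_peaks == 2L),
             n_multimodal = sum(assignments$n_peaks > 2L),
             n_no_peak = sum(assignments$n_peaks == 0L),
             n_retained = sum(assignments$retained),
             n_excluded = sum(!assignments$retained))
    if (length(zc))
        out <- c(out, stats::setNames(as.integer(zc),
                                      paste0("zone_", names(zc))))
    out
}

#' Per-zone taxon composition and coverage
#'
#' For every zone: the summed mean abundance (over the zone's grid depths)
#' of the retained SASVs assigned to it, aggregated by taxon label
#' (missing labels become `"Unknown"`); and the zone's coverage, i.e. the
#' summed abundance of all retained SASVs at the zone's depths as a
#' fraction of the summed abundance of all profiled SASVs there.
#'
#' @param assignments output of [classifyDepthZones()].
#' @param taxonomy named character vector, ASV id to taxon label.
#' @param profiles the profile matrix the assignments were computed from.
#' @param depths numeric depths for the profile columns.
#' @param zones zone table as from [depthZoneTable()].
#' @return list with `composition` (data.frame `zone`, `taxon`,
#'   `abundance`) and `coverage` (data.frame `zone`, `coverage`).
#' @export
zoneComposition <- function(assignments, taxonomy, profiles, depths = NULL,
                            zones = depthZoneTable()) {
    if (is.null(depths)) depths <- as.numeric(colnames(profiles))
    depthZone <- assignDepthZone(depths, zones)
    ret <- assignments[assignments$retained, , drop = FALSE]
    comp <- list(); cov <- list()
    for (z in zones$label) {
        zcols <- which(depthZone == z)
        if (!length(zcols)) next
        zAb <- rowMeans(profiles[, zcols, drop = FALSE])
        inZone <- ret$asv_id[ret$zone == z]
        if (length(inZone)) {
            tax <- taxonomy[inZone]
            tax[is.na(tax) | !nzchar(tax)] <- "Unknown"
            agg <- tapply(zAb[inZone], tax, sum)
            comp[[z]] <- data.frame(zone = z, taxon = names(agg),
                                    abundance = as.numeric(agg))
        }
        total <- sum(zAb)
        covered <- sum(zAb[ret$asv_id])
        cov[[z]] <- data.frame(
            zone = z, coverage = if (total > 0) covered / total else NA_real_)
    }
    list(composition = if (length(comp)) do.call(rbind, comp) else
             data.frame(zone = character(), taxon = character(),
                        abundance = numeric()),
         coverage = do.call(rbind, cov))
}
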