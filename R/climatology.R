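## Monthly climatology of the suspended water-column community: per (depth,
## calendar month), the unweighted mean across years of the per-sample
## relative-abundance vectors, with adjacent-month interpolation of gaps.

.colMeansBy <- function(m, f) {
    f <- factor(f, levels = unique(f))
    sums <- t(rowsum(t(m), f))
    counts <- as.numeric(table(f)[colnames(sums)])
    sweep(sums, 2, counts, "/")
}

#' Build a monthly water-column climatology
#'
#' Averaging proceeds in three steps so that uneven sampling cannot bias the
#' result: replicate samples at one (depth, date) are averaged first, then
#' dates within one (depth, year, month), then years within one (depth,
#' month). Each resulting vector is a convex combination of normalized
#' vectors and so itself sums to one.
#'
#' @param x an [AsvExperiment-class] of water-column samples in `"relative"`
#'   mode.
#' @return a [MonthlyClimatology-class].
#' @export
monthlyClimatology <- function(x) {
    stopifnot(methods::is(x, "AsvExperiment"))
    if (!identical(abundanceMode(x), "relative"))
        stop("monthlyClimatology expects a relative-mode matrix; ",
             "call relativeAbundance() first")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (!all(cd$compartment == "water"))
        stop("monthlyClimatology expects water-column samples only")
    a <- SummarizedExperiment::assay(x)

    ## 1) replicates at one (depth, date)
    k1 <- paste(cd$depth_m, as.character(cd$date_start), sep = "|")
    a1 <- .colMeansBy(a, k1)
    m1 <- cd[match(colnames(a1), k1),
             c("depth_m", "date_start", "month"), drop = FALSE]
    m1$year <- as.integer(format(as.Date(m1$date_start), "%Y"))

    ## 2) dates within one (depth, year, month)
    k2 <- paste(m1$depth_m, m1$year, m1$month, sep = "|")
    a2 <- .colMeansBy(a1, k2)
    m2 <- m1[match(colnames(a2), k2), c("depth_m", "year", "month")]

    ## 3) unweighted mean across years per (depth, month)
    k3 <- paste(m2$depth_m, m2$month, sep = "|")
    a3 <- .colMeansBy(a2, k3)
    m3 <- m2[match(colnames(a3), k3), c("depth_m", "month")]
    nYears <- as.integer(table(factor(k3, levels = colnames(a3)))[colnames(a3)])

    ord <- order(m3$depth_m, m3$month)
    a3 <- a3[, ord, drop = FALSE]
    m3 <- m3[ord, , drop = FALSE]
    colnames(a3) <- .climKey(m3$depth_m, m3$month)
    entries <- data.frame(depth_m = m3$depth_m, month = as.integer(m3$month),
                          n_years = nYears[ord], interpolated = FALSE,
                          row.names = NULL)
    methods::new("MonthlyClimatology", abund = a3, entries = entries)
}

#' Fill missing climatology months from calendar-adjacent months
#'
#' A missing (depth, month) entry is the elementwise mean of the month
#' before and the month after at that depth (calendar-cyclic, so December
#' and January are adjacent), flagged `interpolated`. Only originally
#' observed months are used as sources; interpolated entries never feed
#' further interpolation. If an adjacent month is itself missing the
#' operation fails naming every unfillable (depth, month), unless
#' `allowNearest` is set, in which case the nearest observed month by
#' cyclic distance is used (ties averaged).
#'
#' @param clim a [MonthlyClimatology-class].
#' @param months calendar months each depth should cover; default: every
#'   month observed at any depth.
#' @param allowNearest fall back to the nearest observed month(s) when a
#'   calendar neighbour is missing.
#' @return a [MonthlyClimatology-class] with gaps filled.
#' @export
interpolateMissingMonths <- function(clim, months = NULL,
                                     allowNearest = FALSE) {
    ent <- clim@entries
    if (is.null(months))
        months <- sort(unique(ent$month))
    newCols <- list()
    newEnt <- list()
    failures <- character(0)
    for (d in unique(ent$depth_m)) {
        have <- ent$month[ent$depth_m == d]
        for (m in setdiff(months, have)) {
            prevM <- ((m - 2L) %% 12L) + 1L
            nextM <- (m %% 12L) + 1L
            if (prevM %in% have && nextM %in% have) {
                v <- (clim@abund[, .climKey(d, prevM)] +
                      clim@abund[, .climKey(d, nextM)]) / 2
            } else if (allowNearest) {
                dist <- pmin((have - m) %% 12L, (m - have) %% 12L)
                src <- have[dist == min(dist)]
                v <- rowMeans(clim@abund[, .climKey(d, src), drop = FALSE])
            } else {
                failures <- c(failures, sprintf("(%g m, month %d)", d, m))
                next
            }
            newCols[[.climKey(d, m)]] <- v
            newEnt[[length(newEnt) + 1L]] <- data.frame(
                depth_m = d, month = as.integer(m), n_years = NA_integer_,
                interpolated = TRUE)
        }
    }
    if (length(failures))
        stop("cannot interpolate: adjacent month also missing for ",
             paste(failures, collapse = ", "),
             "; set allowNearest = TRUE to fall back")
    if (!length(newCols))
        return(clim)
    abund <- cbind(clim@abund, do.call(cbind, newCols))
    entries <- rbind(ent, do.call(rbind, newEnt))
    ord <- order(entries$depth_m, entries$month)
    methods::new("MonthlyClimatology",
                 abund = abund[, ord, drop = FALSE],
                 entries = entries[ord, , drop = FALSE])
}

#' Look up one climatology vector
#'
#' @param clim a [MonthlyClimatology-class].
#' @param depth_m,month entry key.
#' @return named numeric vector of mean relative abundances.
#' @export
climatologyAbundance <- function(clim, depth_m, month) {
    key <- .climKey(depth_m, month)
    if (!key %in% colnames(clim@abund))
        stop(sprintf("no climatology entry for depth %g m, month %d",
                     depth_m, month))
    clim@abund[, key]
}

#' Depths covered by a climatology
#'
#' @param clim a [MonthlyClimatology-class].
#' @return sorted numeric vector of depths, metres.
#' @export
climatologyDepths <- function(clim) sort(unique(clim@entries$depth_m))

#' Time-averaged water-column profiles
#'
#' For each ASV, the mean over calendar months of its climatology relative
#' abundance at every depth: the per-SASV depth profile used for abundance
#' filtering and depth-zone classification.
#'
#' @param clim a [MonthlyClimatology-class].
#' @param months months to average over; default, all months present at
#'   every depth.
#' @return numeric matrix, ASVs x depths (columns named by depth).
#' @export
timeAveragedProfiles <- function(clim, months = NULL) {
    ent <- clim@entries
    depths <- climatologyDepths(clim)
    if (is.null(months)) {
        byDepth <- lapply(depths, function(d) ent$month[ent$depth_m == d])
        months <- Reduce(intersect, byDepth)
        if (!length(months))
            stop("no month is covered at every depth; interpolate first")
    }
    out <- vapply(depths, function(d)
        rowMeans(clim@abund[, .climKey(d, months), drop = FALSE]),
        numeric(nrow(clim@abund)))
    colnames(out) <- depths
    out
}
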