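## Synthetic community generator. Plants (i) a piecewise power-law target for
## the summed water-column relative abundance of trap-shared ASVs,
## (ii) depth-zone ecotypes as Gaussian bumps on log10 depth, and (iii) a
## seasonal copiotroph pulse in the trap, so every downstream stage can be
## validated by parameter recovery.

.DEFAULT_DEPTHS <- c(5, 25, 45, 75, 100, 125, 150, 175, 200, 225, 250,
                     300, 400, 500, 770, 1000, 2000, 3000, 4000)

#' Default planted ecotype table
#'
#' Two unimodal ecotypes per grid depth (so that every depth hosts a local
#' community and per-depth renormalisation stays smooth) plus three
#' deep-peaked copiotroph ecotypes (Colwellia-, Moritella- and
#' Halarcobacter-like) that receive the summer-export-pulse multiplier in
#' trap samples. Bump widths default to 5 percent of the peak depth, narrow
#' enough that the planted profile maximum cannot migrate to a neighbouring
#' grid depth under the depth-dependent renormalisation (see the methods
#' vignette).
#'
#' @param depthGrid ordered positive depths, metres.
#' @return data.frame with columns `asv_id`, `taxon`, `peak1`, `peak2`,
#'   `width1`, `width2`, `amp1`, `amp2`, `copiotroph`, `zone`.
#' @export
defaultEcotypes <- function(depthGrid = .DEFAULT_DEPTHS) {
    zones <- depthZoneTable()
    pools <- list(
        Surface = c("Prochlorococcus", "Synechococcus", "SAR11_Ia",
                    "AEGEAN-169"),
        DCM = c("Prochlorococcus_LL", "SAR86", "Ca_Actinomarina"),
        LowerEuphotic = c("SAR11_II", "Nitrosopelagicus"),
        UpperMesopelagic = c("SAR324", "SAR406", "Nitrosopumilaceae"),
        LowerMesopelagic = c("SAR202", "UBA10353", "SAR324"),
        Bathypelagic = c("SAR406", "SAR202", "MGII"))
    rows <- list()
    for (i in seq_along(depthGrid)) {
        z <- depthGrid[i]
        zone <- assignDepthZone(z, zones)
        pool <- pools[[zone]]
        for (k in 1:2) {
            taxon <- pool[((i + k) %% length(pool)) + 1L]
            rows[[length(rows) + 1L]] <- data.frame(
                asv_id = sprintf("eco_%04gm_%d", z, k),
                taxon = taxon, peak1 = z, peak2 = NA_real_,
                width1 = 0.05 * z, width2 = NA_real_,
                amp1 = if (k == 1) 1 else 0.6, amp2 = NA_real_,
                copiotroph = FALSE, zone = zone)
        }
    }
    copio <- data.frame(
        asv_id = c("eco_copio_colwellia", "eco_copio_moritella",
                   "eco_copio_halarcobacter"),
        taxon = c("Colwellia", "Moritella", "Halarcobacter"),
        peak1 = c(2000, 3000, 4000), peak2 = NA_real_,
        width1 = 0.05 * c(2000, 3000, 4000), width2 = NA_real_,
        amp1 = 0.4, amp2 = NA_real_, copiotroph = TRUE,
        zone = "Bathypelagic")
    out <- rbind(do.call(rbind, rows), copio)
    rownames(out) <- NULL
    out
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults are the study
#' conditions the package is validated under: a 19-depth grid spanning
#' 5-4000 m, two years of monthly water-column sampling, 58 consecutive
#' 12-day trap collection intervals, a planted shared-fraction curve with
#' S_75 = 0.829, b_upper = -1.34 above the 250 m transition and
#' b_deep = +0.31 below it, 1e5 reads per sample, and a five-fold summer
#' (July/August) copiotroph pulse in the trap.
#'
#' @param depthGrid strictly increasing positive depths, metres.
#' @param years,months calendar coverage of water-column sampling (one
#'   sample per depth, year and month).
#' @param nTrapIntervals number of consecutive trap collection intervals.
#' @param trapStart first interval start date.
#' @param trapIntervalDays interval length, days.
#' @param sharedCurve list with `sRef` (fraction at `zRef`), `zRef`,
#'   `bUpper`, `zTrans`, `bDeep`: the piecewise target for the summed
#'   water-column relative abundance of trap-shared ASVs, constant above
#'   `zRef`.
#' @param ecotypes data.frame as produced by [defaultEcotypes()]; `peak2`
#'   etc. may be set for bimodal ecotypes, and an optional `disposition`
#'   column is carried through to the truth object untouched.
#' @param sepMonths calendar months whose trap intervals (by midpoint) form
#'   the summer export pulse.
#' @param sepMultiplier factor (>= 1) applied to copiotroph ecotypes in trap
#'   samples during SEP intervals.
#' @param readsPerSample reads drawn per sample (multinomial), or the string
#'   `"noiseless"` for exact expected relative abundances.
#' @param seed default RNG seed used by [simulateDataset()].
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(depthGrid = .DEFAULT_DEPTHS,
                      years = 2015:2016, months = 1:12,
                      nTrapIntervals = 58L,
                      trapStart = as.Date("2014-03-27"),
                      trapIntervalDays = 12,
                      sharedCurve = list(sRef = 0.829, zRef = 75,
                                         bUpper = -1.34, zTrans = 250,
                                         bDeep = 0.31),
                      ecotypes = defaultEcotypes(depthGrid),
                      sepMonths = c(7L, 8L), sepMultiplier = 5,
                      readsPerSample = 1e5, seed = 1L) {
    if (any(diff(depthGrid) <= 0) || any(depthGrid <= 0))
        stop("depthGrid must be strictly increasing and positive")
    sc <- sharedCurve
    if (!all(c("sRef", "zRef", "bUpper", "zTrans", "bDeep") %in% names(sc)))
        stop("sharedCurve must have sRef, zRef, bUpper, zTrans, bDeep")
    if (sc$sRef <= 0 || sc$sRef > 1)
        stop("sharedCurve$sRef must lie in (0, 1]")
    span <- range(depthGrid)
    if (sc$zRef < span[1] || sc$zRef > span[2] ||
        sc$zTrans < span[1] || sc$zTrans > span[2])
        stop("zRef and zTrans must lie within the depth grid span")
    if (anyDuplicated(ecotypes$asv_id))
        stop("ecotype asv_id values must be unique")
    if (any(ecotypes$amp1 <= 0, na.rm = TRUE) ||
        any(ecotypes$amp2 <= 0, na.rm = TRUE))
        stop("ecotype amplitudes must be positive")
    if (sepMultiplier < 1)
        stop("sepMultiplier must be >= 1")
    if (!(identical(readsPerSample, "noiseless") ||
          (is.numeric(readsPerSample) && readsPerSample >= 1)))
        stop("readsPerSample must be a positive count or \"noiseless\"")
    cfg <- list(depthGrid = depthGrid, years = years, months = months,
                nTrapIntervals = as.integer(nTrapIntervals),
                trapStart = as.Date(trapStart),
                trapIntervalDays = trapIntervalDays,
                sharedCurve = sc, ecotypes = ecotypes,
                sepMonths = as.integer(sepMonths),
                sepMultiplier = sepMultiplier,
                readsPerSample = readsPerSample, seed = as.integer(seed))
    ## the target must be a feasible fraction everywhere, checked up front
    s <- vapply(depthGrid, function(z) .sharedTarget(sc, z), numeric(1))
    if (any(s > 1 + 1e-12) || any(s <= 0))
        stop("planted shared fraction leaves (0, 1] at depth(s) ",
             paste(depthGrid[s > 1 + 1e-12 | s <= 0], collapse = ", "))
    class(cfg) <- "SimConfig"
    cfg
}

.sharedTarget <- function(sc, z) {
    if (z < sc$zRef) {
        sc$sRef
    } else if (z <= sc$zTrans) {
        sc$sRef * (z / sc$zRef)^sc$bUpper
    } else {
        sc$sRef * (sc$zTrans / sc$zRef)^sc$bUpper * (z / sc$zTrans)^sc$bDeep
    }
}

#' Planted shared fraction at a depth
#'
#' Evaluates the piecewise power-law target S(Z): constant at `sRef` above
#' the reference depth, `sRef * (Z/zRef)^bUpper` between the reference and
#' transition depths, and `S(zTrans) * (Z/zTrans)^bDeep` below the
#' transition; continuous at the transition.
#'
#' @param cfg a [simConfig()] object.
#' @param depth_m depth(s) in metres, within the grid span.
#' @return numeric fraction(s) in (0, 1].
#' @export
expectedSharedFraction <- function(cfg, depth_m) {
    span <- range(cfg$depthGrid)
    if (any(depth_m < span[1] | depth_m > span[2]))
        stop(sprintf("depth outside the simulated span %g-%g m",
                     span[1], span[2]))
    vapply(depth_m, function(z) .sharedTarget(cfg$sharedCurve, z), numeric(1))
}

## Gaussian bump on log10 depth; width is expressed in metres at the peak.
.bump <- function(z, peak, width) {
    sigma <- log10(1 + width / peak)
    exp(-log10(z / peak)^2 / (2 * sigma^2))
}

.ecotypeShapes <- function(ecotypes, depthGrid) {
    g <- matrix(0, nrow(ecotypes), length(depthGrid),
                dimnames = list(ecotypes$asv_id, depthGrid))
    for (i in seq_len(nrow(ecotypes))) {
        e <- ecotypes[i, ]
        g[i, ] <- e$amp1 * .bump(depthGrid, e$peak1, e$width1)
        if (!is.na(e$peak2))
            g[i, ] <- g[i, ] + e$amp2 * .bump(depthGrid, e$peak2, e$width2)
    }
    g
}

.randomSequences <- function(n, len = 250L) {
    repeat {
        seqs <- vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = ""), character(1))
        if (!anyDuplicated(seqs)) return(seqs)
    }
}

#' Simulate a paired water-column / sediment-trap dataset
#'
#' At every grid depth the expected water community is partitioned into
#' "shared" ecotype ASVs, whose summed relative abundance equals the planted
#' piecewise power law S(Z) exactly, and one depth-specific unshared filler
#' ASV absorbing the remaining 1 - S(Z). Ecotype shares within the shared
#' pool follow their Gaussian depth bumps. Trap samples contain all ecotype
#' ASVs (never the fillers) with equal base weights; copiotroph ecotypes are
#' multiplied by `sepMultiplier` during summer-export-pulse intervals before
#' renormalisation. Counts are drawn multinomially with `readsPerSample`
#' reads, or exact expected fractions are emitted in `"noiseless"` mode.
#' Flux records are generated so that SEP intervals exceed 1.5x the
#' reference means for both particulate carbon and nitrogen and non-SEP
#' intervals do not.
#'
#' @param cfg a [simConfig()] object.
#' @param seed integer RNG seed; defaults to `cfg$seed`. The same config and
#'   seed reproduce the dataset bit-identically.
#' @return list with elements `water` and `trap` ([AsvExperiment-class]s),
#'   `flux` (data.frame), `truth` (planted ground truth: per-depth target
#'   shared fraction, ecotype table with intended zones, SEP interval ids
#'   and SEP-enriched ASV ids) and `config`.
#' @examples
#' cfg <- simConfig(readsPerSample = "noiseless")
#' sim <- simulateDataset(cfg)
#' sim$truth$sharedFraction[1:4, ]
#' @export
simulateDataset <- function(cfg, seed = cfg$seed) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(seed)
    depths <- cfg$depthGrid
    nd <- length(depths)
    eco <- cfg$ecotypes
    g <- .ecotypeShapes(eco, depths)
    G <- colSums(g)
    S <- expectedSharedFraction(cfg, depths)

    fillerIds <- sprintf("filler_%04gm", depths)
    asvIds <- c(eco$asv_id, fillerIds)
    sequences <- stats::setNames(.randomSequences(length(asvIds)), asvIds)
    taxonomy <- stats::setNames(
        c(eco$taxon, rep("Unassigned", nd)), asvIds)

    ## expected water community per depth (columns sum to 1 exactly)
    expWater <- matrix(0, length(asvIds), nd,
                       dimnames = list(asvIds, depths))
    for (j in seq_len(nd)) {
        expWater[eco$asv_id, j] <- S[j] * g[, j] / G[j]
        expWater[fillerIds[j], j] <- 1 - S[j]
    }

    ## water samples: one per (depth, year, month)
    grid <- expand.grid(depth = depths, month = cfg$months,
                        year = cfg$years, KEEP.OUT.ATTRS = FALSE)
    waterIds2 <- sprintf("W%gm.%d.%02d", grid$depth, grid$year, grid$month)
    waterMd <- data.frame(
        sample_id = waterIds2, compartment = "water",
        depth_m = grid$depth,
        date_start = as.Date(sprintf("%d-%02d-15", grid$year, grid$month)),
        month = as.integer(grid$month))
    depthIdx <- match(grid$depth, depths)

    noiseless <- identical(cfg$readsPerSample, "noiseless")
    drawCols <- function(expCols) {
        if (noiseless) return(expCols)
        n <- as.integer(cfg$readsPerSample)
        apply(expCols, 2, function(p) as.numeric(stats::rmultinom(1, n, p)))
    }
    waterAbund <- drawCols(expWater[, depthIdx, drop = FALSE])
    dimnames(waterAbund) <- list(asvIds, waterIds2)
    water <- AsvExperiment(waterAbund, sequences, waterMd,
                           mode = if (noiseless) "relative" else "counts",
                           taxonomy = taxonomy)

    ## trap intervals
    k <- seq_len(cfg$nTrapIntervals)
    starts <- cfg$trapStart + (k - 1L) * cfg$trapIntervalDays
    ends <- starts + cfg$trapIntervalDays
    mids <- starts + floor(cfg$trapIntervalDays / 2)
    midMonth <- as.integer(format(mids, "%m"))
    isSep <- midMonth %in% cfg$sepMonths
    trapIds2 <- sprintf("T%03d", k)
    trapMd <- data.frame(
        sample_id = trapIds2, compartment = "trap", depth_m = 4000,
        date_start = starts, date_end = ends, month = midMonth)

    baseW <- rep(1, nrow(eco))
    expTrap <- vapply(k, function(i) {
        w <- baseW
        if (isSep[i]) w[eco$copiotroph] <- w[eco$copiotroph] * cfg$sepMultiplier
        w / sum(w)
    }, numeric(nrow(eco)))
    dimnames(expTrap) <- list(eco$asv_id, trapIds2)
    trapAbund <- drawCols(expTrap)
    dimnames(trapAbund) <- dimnames(expTrap)
    trap <- AsvExperiment(trapAbund, sequences[eco$asv_id], trapMd,
                          mode = if (noiseless) "relative" else "counts",
                          taxonomy = taxonomy[eco$asv_id])

    ## flux records: SEP intervals exceed 1.5x both references, others don't
    pcRef <- 1.6; pnRef <- 0.22  # mg m-2 d-1, deep-trap scale
    pcRatio <- ifelse(isSep, stats::runif(length(k), 1.7, 2.4),
                             stats::runif(length(k), 0.5, 1.35))
    pnRatio <- ifelse(isSep, stats::runif(length(k), 1.6, 2.2),
                             stats::runif(length(k), 0.5, 1.35))
    flux <- data.frame(
        sample_id = trapIds2, interval_start = starts, interval_end = ends,
        pc_flux = pcRatio * pcRef, pn_flux = pnRatio * pnRef,
        pc_ref_mean = pcRef, pn_ref_mean = pnRef)

    eco_truth <- eco
    if (!"zone" %in% colnames(eco_truth))
        eco_truth$zone <- assignDepthZone(eco_truth$peak1, depthZoneTable())
    truth <- list(
        sharedFraction = data.frame(depth_m = depths, shared_fraction = S),
        ecotypes = eco_truth,
        expectedWater = expWater,
        expectedTrap = expTrap,
        sepIntervals = trapIds2[isSep],
        sepAsvs = eco$asv_id[eco$copiotroph],
        curve = cfg$sharedCurve)
    list(water = water, trap = trap, flux = flux, truth = truth,
         config = cfg)
}

#' Write a simulated dataset in the formats readAsvDataset() consumes
#'
#' Emits `water_counts.tsv` / `water.fasta` / `water_metadata.csv`, the trap
#' equivalents, `flux.csv` and `truth.json` under `dir`.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeSimulatedDataset <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    exportAsvDataset(sim$water, p("water_counts.tsv"), p("water.fasta"),
                     p("water_metadata.csv"))
    exportAsvDataset(sim$trap, p("trap_counts.tsv"), p("trap.fasta"),
                     p("trap_metadata.csv"))
    utils::write.csv(sim$flux, p("flux.csv"), row.names = FALSE,
                     quote = FALSE)
    truth <- sim$truth
    truth$expectedWater <- NULL  # matrices stay in memory, not in JSON
    truth$expectedTrap <- NULL
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    invisible(dir)
}
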