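## Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

## deterministic fake sequences: unique per id, alphabet ACGT
fakeSeqs <- function(ids, len = 40L) {
    stats::setNames(vapply(seq_along(ids), function(i) {
        set.seed(1000L + i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
    }, character(1)), ids)
}

## small AsvExperiment builder
makeExperiment <- function(mat, compartment = "water", depth_m = 75,
                           date_start = as.Date("2015-03-10"),
                           date_end = NULL, mode = "counts",
                           seqs = NULL, taxonomy = NULL) {
    if (is.null(seqs)) seqs <- fakeSeqs(rownames(mat))
    md <- data.frame(sample_id = colnames(mat), compartment = compartment,
                     depth_m = depth_m, date_start = date_start)
    if (!is.null(date_end)) md$date_end <- date_end
    AsvExperiment(mat, seqs, md, mode = mode, taxonomy = taxonomy)
}

## water dataset spanning depths x (year, month): each column is the same
## per-depth relative vector `profile[, depth]` (ASVs x depths)
makeWaterSeries <- function(profile, depths, years = 2015:2016,
                            months = 1:12, seqs = NULL) {
    cols <- expand.grid(depth = depths, month = months, year = years)
    mat <- profile[, match(cols$depth, depths), drop = FALSE]
    colnames(mat) <- sprintf("W%g.%d.%02d", cols$depth, cols$year,
                             cols$month)
    if (is.null(seqs)) seqs <- fakeSeqs(rownames(profile))
    md <- data.frame(sample_id = colnames(mat), compartment = "water",
                     depth_m = cols$depth,
                     date_start = as.Date(sprintf("%d-%02d-15", cols$year,
                                                  cols$month)))
    AsvExperiment(mat, seqs, md, mode = "relative")
}

## independent oracle for the power-law fit: dense profile over b with the
## conditionally optimal s (linear least squares given b)
gridSearchB <- function(z, y, zRef, bGrid = seq(-3, 3, by = 0.001)) {
    sse <- vapply(bGrid, function(b) {
        x <- (z / zRef)^b
        s <- sum(x * y) / sum(x * x)
        sum((y - s * x)^2)
    }, numeric(1))
    bGrid[which.min(sse)]
}

## hand-evaluated Welch statistics (oracle, independent of stats::t.test)
welchOracle <- function(x, y) {
    nx <- length(x); ny <- length(y)
    vx <- sum((x - mean(x))^2) / (nx - 1)
    vy <- sum((y - mean(y))^2) / (ny - 1)
    se2 <- vx / nx + vy / ny
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, df = df, p = p)
}

## planted ecotype panel for classification recovery: 100 unimodal +
## 20 bimodal (10 retained by the single-peak-above-mean rule, 5 by the
## same-zone rule, 5 satisfying neither)
classificationEcotypes <- function(depthGrid = c(5, 25, 45, 75, 100, 125,
                                                 150, 175, 200, 225, 250,
                                                 300, 400, 500, 770, 1000,
                                                 2000, 3000, 4000)) {
    zones <- depthZoneTable()
    uni <- do.call(rbind, lapply(1:100, function(i) {
        z <- depthGrid[((i - 1L) %% length(depthGrid)) + 1L]
        data.frame(asv_id = sprintf("uni_%03d", i), taxon = "TaxonU",
                   peak1 = z, peak2 = NA_real_, width1 = 0.05 * z,
                   width2 = NA_real_,
                   amp1 = if (i %% 2) 1 else 0.7, amp2 = NA_real_,
                   copiotroph = FALSE, zone = assignDepthZone(z, zones),
                   disposition = "retained_single")
    }))
    bi <- function(ids, p1, p2, a2, disp, zoneOf = "major") {
        zone <- switch(zoneOf,
                       major = assignDepthZone(p1, zones),
                       none = NA_character_)
        data.frame(asv_id = ids, taxon = "TaxonB", peak1 = p1, peak2 = p2,
                   width1 = 0.05 * p1, width2 = 0.05 * p2, amp1 = 1,
                   amp2 = a2, copiotroph = FALSE, zone = zone,
                   disposition = disp)
    }
    rule1 <- bi(sprintf("bi1_%02d", 1:10),
                p1 = c(25, 45, 100, 125, 150, 175, 200, 225, 300, 400),
                p2 = c(770, 1000, 2000, 3000, 4000, 500, 770, 45, 5, 125),
                a2 = 0.003, disp = "retained_rule1")
    rule2 <- bi(sprintf("bi2_%02d", 1:5),
                p1 = c(5, 100, 225, 250, 2000),
                p2 = c(45, 150, 300, 500, 4000),
                a2 = 0.8, disp = "retained_rule2")
    neither <- bi(sprintf("bix_%02d", 1:5),
                  p1 = c(100, 125, 150, 200, 225),
                  p2 = c(770, 1000, 2000, 3000, 4000),
                  a2 = 0.8, disp = "excluded", zoneOf = "none")
    out <- rbind(uni, rule1, rule2, neither)
    rownames(out) <- NULL
    out
}
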