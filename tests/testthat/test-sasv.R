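## A small fixed world: water at 75 m (March) holds {B, C, D} (A absent),
## the trap sample holds {A, B, C}. Shared set must be {B, C}.
makeWorld <- function(seqs = fakeSeqs(c("A", "B", "C", "D"))) {
    water <- matrix(c(0, 0.2, 0.1, 0.7), ncol = 1,
                    dimnames = list(c("A", "B", "C", "D"), "w1"))
    wmd <- data.frame(sample_id = "w1", compartment = "water", depth_m = 75,
                      date_start = as.Date("2015-03-10"))
    wexp <- AsvExperiment(water, seqs, wmd, mode = "relative")
    clim <- monthlyClimatology(wexp)
    trap <- matrix(c(0.8, 0.05, 0.15, 0), ncol = 1,
                   dimnames = list(c("A", "B", "C", "D"), "t1"))
    tmd <- data.frame(sample_id = "t1", compartment = "trap",
                      depth_m = 4000, date_start = as.Date("2015-03-01"),
                      date_end = as.Date("2015-03-13"))
    texp <- AsvExperiment(trap, seqs, tmd, mode = "relative")
    list(clim = clim, trap = texp, waterSeqs = seqs)
}

test_that("SASVs are the sequence-identical presence intersection", {
    w <- makeWorld()
    ss <- identifySasvs(w$trap, "t1", w$clim, 75, 3,
                        waterSequences = w$waterSeqs)
    expect_identical(sasvIds(ss), c("B", "C"))
    expect_equal(waterFraction(ss, w$clim), 0.3)
    expect_equal(trapFraction(ss, w$trap), 0.2)
})

test_that("disjoint compartments give an empty set with zero fractions", {
    w <- makeWorld()
    ## rename trap sequences so nothing matches
    trap2 <- w$trap
    SummarizedExperiment::rowData(trap2)$dna_sequence <-
        unname(fakeSeqs(paste0("other", 1:4), len = 41L))
    ss <- identifySasvs(trap2, "t1", w$clim, 75, 3,
                        waterSequences = w$waterSeqs)
    expect_length(sasvIds(ss), 0)
    expect_identical(waterFraction(ss, w$clim), 0)
    expect_identical(trapFraction(ss, trap2), 0)
})

test_that("complete sharing gives fractions of one", {
    seqs <- fakeSeqs(c("A", "B", "C", "D"))
    water <- matrix(c(0.1, 0.2, 0.3, 0.4), ncol = 1,
                    dimnames = list(names(seqs), "w1"))
    wmd <- data.frame(sample_id = "w1", compartment = "water", depth_m = 75,
                      date_start = as.Date("2015-03-10"))
    clim <- monthlyClimatology(AsvExperiment(water, seqs, wmd,
                                             mode = "relative"))
    trap <- matrix(c(0.25, 0.25, 0.25, 0.25), ncol = 1,
                   dimnames = list(names(seqs), "t1"))
    tmd <- data.frame(sample_id = "t1", compartment = "trap",
                      depth_m = 4000, date_start = as.Date("2015-03-05"))
    texp <- AsvExperiment(trap, seqs, tmd, mode = "relative")
    ss <- identifySasvs(texp, "t1", clim, 75, 3, waterSequences = seqs)
    expect_lt(abs(waterFraction(ss, clim) - 1), 1e-9)
    expect_lt(abs(trapFraction(ss, texp) - 1), 1e-9)
})

test_that("sequences differing only at a masked N match only as wildcard", {
    seqsW <- fakeSeqs(c("A", "B", "C", "D"))
    seqsT <- seqsW
    ## plant an N at the 21st position from the end of trap ASV B
    pos <- nchar(seqsT[["B"]]) - 20L
    substr(seqsT[["B"]], pos, pos) <- "N"
    w <- makeWorld()
    trapN <- w$trap
    SummarizedExperiment::rowData(trapN)$dna_sequence <- unname(seqsT)
    exact <- identifySasvs(trapN, "t1", w$clim, 75, 3,
                           waterSequences = seqsW)
    expect_identical(sasvIds(exact), "C")
    wild <- identifySasvs(trapN, "t1", w$clim, 75, 3,
                          waterSequences = seqsW, nWildcard = TRUE)
    expect_identical(sasvIds(wild), c("B", "C"))
})

test_that("fractions are monotone under growing the shared set", {
    w <- makeWorld()
    full <- identifySasvs(w$trap, "t1", w$clim, 75, 3,
                          waterSequences = w$waterSeqs)
    sub <- methods::new("SasvSet", trapSampleId = "t1", waterDepth = 75,
                        month = 3L, trapIds = "B", waterIds = "B")
    expect_lte(waterFraction(sub, w$clim), waterFraction(full, w$clim))
    expect_lte(trapFraction(sub, w$trap), trapFraction(full, w$trap))
})

test_that("an ASV shared at several depths counts fully at each", {
    seqs <- fakeSeqs(c("A", "B"))
    water <- matrix(c(0.6, 0.4, 0.3, 0.7), nrow = 2,
                    dimnames = list(c("A", "B"), c("w1", "w2")))
    wmd <- data.frame(sample_id = c("w1", "w2"), compartment = "water",
                      depth_m = c(100, 200),
                      date_start = as.Date("2015-03-10"))
    clim <- monthlyClimatology(AsvExperiment(water, seqs, wmd,
                                             mode = "relative"))
    trap <- matrix(c(0.9, 0.1), ncol = 1,
                   dimnames = list(c("A", "B"), "t1"))
    tmd <- data.frame(sample_id = "t1", compartment = "trap",
                      depth_m = 4000, date_start = as.Date("2015-03-05"))
    texp <- AsvExperiment(trap, seqs, tmd, mode = "relative")
    tbl <- sasvFractionTable(texp, clim, waterSequences = seqs)
    ## A and B are present at both depths: full trap abundance both times,
    ## so the per-depth trap fractions sum above 1
    expect_equal(tbl$trap_fraction, c(1, 1))
    expect_gt(sum(tbl$trap_fraction), 1)
    expect_equal(tbl$water_fraction, c(1, 1))
})

test_that("sasvFractionTable agrees with per-set identification", {
    cfg <- simConfig(years = 2015, months = 1:12, nTrapIntervals = 3L,
                     readsPerSample = 3000)
    sim <- simulateDataset(cfg, seed = 21)
    water <- relativeAbundance(sim$water)
    trap <- relativeAbundance(sim$trap)
    clim <- monthlyClimatology(water)
    seqs <- stats::setNames(
        as.character(SummarizedExperiment::rowData(water)$dna_sequence),
        rownames(water))
    tbl <- sasvFractionTable(trap, clim, waterSequences = seqs)
    for (r in c(1L, 11L, nrow(tbl))) {
        ss <- identifySasvs(trap, tbl$sample_id[r], clim, tbl$depth_m[r],
                            tbl$month[r], waterSequences = seqs)
        expect_equal(tbl$water_fraction[r], waterFraction(ss, clim))
        expect_equal(tbl$trap_fraction[r], trapFraction(ss, trap))
        expect_identical(tbl$n_sasvs[r], length(sasvIds(ss)))
    }
})

test_that("on noiseless data the water fraction equals the planted curve", {
    cfg <- simConfig(years = 2015, months = 1:12, nTrapIntervals = 2L,
                     readsPerSample = "noiseless")
    sim <- simulateDataset(cfg)
    clim <- monthlyClimatology(sim$water)
    seqs <- stats::setNames(as.character(
        SummarizedExperiment::rowData(sim$water)$dna_sequence),
        rownames(sim$water))
    tbl <- sasvFractionTable(sim$trap, clim, waterSequences = seqs)
    expect_equal(tbl$water_fraction,
                 expectedSharedFraction(cfg, tbl$depth_m),
                 tolerance = 1e-12)
})

test_that("profileOverTime computes mean, sample sd and n per depth", {
    tbl <- data.frame(sample_id = c("t1", "t2", "t3"),
                      depth_m = c(100, 100, 200),
                      water_fraction = c(0.2, 0.4, 0.5))
    prof <- profileOverTime(tbl)
    expect_equal(prof$mean, c(0.3, 0.5))
    expect_equal(prof$sd, c(sd(c(0.2, 0.4)), 0))  # singleton sd = 0
    expect_equal(prof$sd[1], 0.1414214, tolerance = 1e-6)
    expect_identical(prof$n, c(2L, 1L))
    ## permutation invariance
    expect_equal(profileOverTime(tbl[c(3, 1, 2), ]), prof)
})

test_that("richness is the size of the per-depth union of SASV sets", {
    mk <- function(ids, depth) methods::new("SasvSet",
        trapSampleId = "t", waterDepth = depth, month = 1L,
        trapIds = ids, waterIds = ids)
    sets <- list(mk(c("A", "B"), 100), mk(c("B", "C"), 100),
                 mk(character(0), 200))
    r <- sasvRichnessByDepth(sets)
    expect_identical(r$richness[r$depth_m == 100], 3L)
    expect_identical(r$richness[r$depth_m == 200], 0L)
    ## duplicating an interval's set leaves the union unchanged
    r2 <- sasvRichnessByDepth(c(sets, list(mk(c("A", "B"), 100))))
    expect_identical(r2$richness[r2$depth_m == 100], 3L)
})
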