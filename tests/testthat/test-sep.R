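mkFlux <- function(pcRatio, pnRatio, pcRef = 2, pnRef = 0.25) {
    n <- length(pcRatio)
    start <- as.Date("2014-03-27") + 12 * (seq_len(n) - 1)
    data.frame(sample_id = sprintf("T%03d", seq_len(n)),
               interval_start = start, interval_end = start + 12,
               pc_flux = pcRatio * pcRef, pn_flux = pnRatio * pnRef,
               pc_ref_mean = pcRef, pn_ref_mean = pnRef)
}

test_that("SEP flagging is the inclusive AND of both flux ratios", {
    cal <- flagSep(mkFlux(c(1.6, 1.6, 1.5, 1.2), c(1.7, 1.2, 1.5, 1.7)))
    expect_identical(cal$is_sep, c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(cal$pc_ratio, c(1.6, 1.6, 1.5, 1.2))
    ## --any relaxation: either ratio suffices
    calAny <- flagSep(mkFlux(c(1.6, 1.6, 1.5, 1.2),
                             c(1.7, 1.2, 1.5, 1.7)), any = TRUE)
    expect_identical(calAny$is_sep, c(TRUE, TRUE, TRUE, TRUE))
    ## missing flux -> NA flag with a warning, not an error
    fx <- mkFlux(c(1.6, NA), c(1.7, 1.7))
    expect_warning(calNA <- flagSep(fx), "missing flux")
    expect_identical(calNA$is_sep, c(TRUE, NA))
    ## invalid reference means
    bad <- mkFlux(1.6, 1.7); bad$pc_ref_mean <- 0
    expect_error(flagSep(bad), "positive")
})

test_that("the Welch test matches the hand-evaluated oracle", {
    x <- c(10, 12, 14); y <- c(1, 2, 3)
    got <- welchTTest(x, y)
    want <- welchOracle(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_equal(got$t, 7.745967, tolerance = 1e-3)
    expect_equal(got$df, 2.941176, tolerance = 1e-3)
    ## a second, less tidy case
    x2 <- c(0.31, 0.12, 0.55, 0.44, 0.29); y2 <- c(0.21, 0.23, 0.18)
    got2 <- welchTTest(x2, y2)
    want2 <- welchOracle(x2, y2)
    expect_equal(got2$t, want2$t, tolerance = 1e-10)
    expect_equal(got2$df, want2$df, tolerance = 1e-10)
    expect_equal(got2$p_value, want2$p, tolerance = 1e-10)
})

test_that("the Welch test honours its symmetries and degeneracies", {
    x <- c(10, 12, 14); y <- c(1, 2, 3)
    expect_identical(welchTTest(x, x)$t, 0)
    expect_identical(welchTTest(x, x)$p_value, 1)
    ab <- welchTTest(x, y); ba <- welchTTest(y, x)
    expect_equal(ba$t, -ab$t)
    expect_equal(ba$p_value, ab$p_value)
    ## undefined, not fatal
    expect_match(welchTTest(1, y)$note, "fewer than 2")
    expect_match(welchTTest(c(2, 2, 2), c(3, 3, 3))$note, "zero variance")
    expect_true(is.na(welchTTest(c(2, 2, 2), c(3, 3, 3))$p_value))
    ## one constant group is still testable
    expect_false(is.na(welchTTest(c(2, 2, 2), y)$p_value))
})

mkTrap <- function(mat, start = as.Date("2014-03-27")) {
    n <- ncol(mat)
    colnames(mat) <- sprintf("T%03d", seq_len(n))
    starts <- start + 12 * (seq_len(n) - 1)
    md <- data.frame(sample_id = colnames(mat), compartment = "trap",
                     depth_m = 4000, date_start = starts,
                     date_end = starts + 12)
    AsvExperiment(mat, fakeSeqs(rownames(mat)), md, mode = "relative")
}

test_that("enrichment combines significance with the direction gate", {
    set.seed(31)
    n <- 20L; nSep <- 8L
    up <- c(rnorm(nSep, 0.30, 0.01), rnorm(n - nSep, 0.10, 0.01))
    down <- c(rnorm(nSep, 0.10, 0.01), rnorm(n - nSep, 0.30, 0.01))
    flat <- rnorm(n, 0.2, 0.01)
    rest <- 1 - (up + down + flat)
    mat <- rbind(up = up, down = down, flat = flat, rest = rest)
    trap <- mkTrap(mat)
    cal <- flagSep(mkFlux(c(rep(2, nSep), rep(1, n - nSep)),
                          c(rep(2, nSep), rep(1, n - nSep))))
    res <- enrichedSasvs(trap, cal, alpha = 0.05)
    expect_true(res$enriched[res$asv_id == "up"])
    ## "down" is highly significant but fails the direction gate
    expect_lt(res$p_value[res$asv_id == "down"], 0.05)
    expect_false(res$enriched[res$asv_id == "down"])
    expect_false(res$enriched[res$asv_id == "flat"])

    ## interval order invariance
    perm <- sample(ncol(trap))
    res2 <- enrichedSasvs(trap[, perm], cal, alpha = 0.05)
    res2 <- res2[match(res$asv_id, res2$asv_id), ]
    expect_equal(res$p_value, res2$p_value, tolerance = 1e-12)
    expect_identical(res$enriched, res2$enriched)

    ## BH-corrected enriched set is a subset of the uncorrected one
    resF <- enrichedSasvs(trap, cal, alpha = 0.05, fdr = TRUE)
    expect_true(all(resF$asv_id[resF$enriched] %in%
                    res$asv_id[res$enriched]))

    ## too few intervals in a stratum is an error
    cal1 <- cal; cal1$is_sep <- c(TRUE, rep(FALSE, n - 1L))
    expect_error(enrichedSasvs(trap, cal1), "at least 2")
})

test_that("planted SEP enrichment is recovered from a simulated run", {
    cfg <- simConfig(years = 2015, months = 1:12, nTrapIntervals = 30L,
                     readsPerSample = 1e4)
    sim <- simulateDataset(cfg, seed = 41)
    trap <- relativeAbundance(sim$trap)
    cal <- flagSep(sim$flux)
    res <- enrichedSasvs(trap, cal)
    hit <- res$asv_id[res$enriched]
    expect_true(all(sim$truth$sepAsvs %in% hit))
    ## nothing outside the planted copiotrophs should be *enriched*
    ## (non-copiotrophs are diluted during SEP, failing the direction gate)
    expect_identical(sort(hit), sort(sim$truth$sepAsvs))
})

test_that("null labels produce calibrated rejection rates", {
    ## moderate-size calibration check; the acceptance suite runs the full
    ## 1000-replicate version
    set.seed(53)
    nrep <- 300L
    pvals <- replicate(nrep, welchTTest(rnorm(10), rnorm(10))$p_value)
    rate <- mean(pvals < 0.05)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrep))
})
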