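test_that("the default zone map covers the canonical grid exactly", {
    grid <- c(5, 25, 45, 75, 100, 125, 150, 175, 200, 225, 250, 300, 400,
              500, 770, 1000, 2000, 3000, 4000)
    zones <- assignDepthZone(grid)
    expect_identical(zones[grid <= 75], rep("Surface", 4))
    expect_identical(zones[grid %in% c(100, 125, 150)], rep("DCM", 3))
    expect_identical(zones[grid %in% c(175, 200)], rep("LowerEuphotic", 2))
    expect_identical(zones[grid %in% c(225, 250, 300, 400, 500)],
                     rep("UpperMesopelagic", 5))
    expect_identical(zones[grid %in% c(770, 1000)],
                     rep("LowerMesopelagic", 2))
    expect_identical(zones[grid >= 2000], rep("Bathypelagic", 3))
    ## off-grid depths between bounds go to the nearest bound midpoint
    expect_identical(assignDepthZone(85), "DCM")
    expect_identical(assignDepthZone(600), "UpperMesopelagic")
})

test_that("the abundance filter is inclusive at the 0.1% boundary", {
    prof <- rbind(lo = c(5e-04, 2e-04, 1e-04),
                  at = c(0.001, 2e-04, 1e-04),
                  hi = c(0.01, 0.002, 5e-04))
    colnames(prof) <- c(75, 100, 125)
    expect_identical(rownames(selectAbundant(prof)), c("at", "hi"))
    expect_identical(nrow(selectAbundant(prof, threshold = 0)), 3L)
})

test_that("depth maxima follow the strict-inequality and plateau rules", {
    d3 <- c(75, 100, 125)
    expect_identical(findDepthMaxima(c(1, 3, 2), d3), 100)
    ## monotone profile: edge convention both ways
    d4 <- c(75, 100, 125, 150)
    expect_identical(findDepthMaxima(c(5, 4, 3, 2), d4), 75)
    expect_identical(findDepthMaxima(c(5, 4, 3, 2), d4,
                                     edgePeaks = FALSE), numeric(0))
    ## bimodal
    d5 <- c(75, 100, 125, 150, 175)
    expect_identical(findDepthMaxima(c(1, 5, 2, 6, 1), d5), c(100, 150))
    ## plateau counts once, at its shallowest depth
    expect_identical(findDepthMaxima(c(1, 4, 4, 1), d4), 100)
    ## constant profile has no peaks; short profiles error
    expect_identical(findDepthMaxima(c(2, 2, 2), d3), numeric(0))
    expect_error(findDepthMaxima(c(1, 2), c(75, 100)), "at least 3")
})

test_that("bimodal retention rules assign the documented zones", {
    d5 <- c(75, 100, 125, 150, 175)
    prof <- rbind(
        rule2 = c(0.01, 0.30, 0.02, 0.25, 0.01),  # peaks 100 & 150, both DCM
        uni = c(0.01, 0.02, 0.30, 0.02, 0.01))
    colnames(prof) <- d5
    out <- classifyDepthZones(prof)
    expect_true(out$retained[out$asv_id == "rule2"])
    expect_identical(out$zone[out$asv_id == "rule2"], "DCM")
    expect_true(out$retained[out$asv_id == "uni"])
    expect_identical(out$zone[out$asv_id == "uni"], "DCM")

    ## rule 1: peaks at 25 m (above the depth-averaged mean) and 770 m
    ## (below it) -> retained with the zone of the sole exceeding peak
    d4 <- c(25, 100, 770, 1000)
    prof1 <- rbind(r1 = c(0.50, 0.01, 0.03, 0.01))
    colnames(prof1) <- d4
    out1 <- classifyDepthZones(prof1)
    expect_true(out1$retained)
    expect_identical(out1$zone, "Surface")
    expect_identical(out1$n_peaks, 2L)

    ## both peaks above the mean in different zones -> excluded
    prof2 <- rbind(x = c(0.50, 0.01, 0.45, 0.01))
    colnames(prof2) <- d4
    out2 <- classifyDepthZones(prof2)
    expect_false(out2$retained)
    expect_identical(out2$reason, "bimodal_unresolved")

    ## more than two peaks -> excluded as multimodal
    d7 <- c(25, 75, 100, 150, 200, 770, 1000)
    prof3 <- rbind(m = c(0.4, 0.01, 0.3, 0.01, 0.25, 0.01, 0.2))
    colnames(prof3) <- d7
    out3 <- classifyDepthZones(prof3)
    expect_false(out3$retained)
    expect_identical(out3$reason, "multimodal")
})

test_that("classification bookkeeping is exactly conserved", {
    set.seed(23)
    depths <- c(5, 25, 75, 100, 150, 200, 300, 500, 1000, 4000)
    prof <- matrix(runif(60 * length(depths)), nrow = 60,
                   dimnames = list(sprintf("a%02d", 1:60), depths))
    out <- classifyDepthZones(prof)
    ct <- zoneCounts(out)
    expect_identical(ct[["n_single"]] + ct[["n_bimodal"]] +
                     ct[["n_multimodal"]] + ct[["n_no_peak"]],
                     ct[["n_abundant"]])
    expect_identical(ct[["n_retained"]] + ct[["n_excluded"]],
                     ct[["n_abundant"]])
    expect_identical(sum(out$retained), ct[["n_retained"]])
    ## invariance to a common positive rescaling
    out2 <- classifyDepthZones(37 * prof)
    expect_identical(out$retained, out2$retained)
    expect_identical(out$zone, out2$zone)
    expect_identical(out$peak_depths, out2$peak_depths)
})

test_that("zone composition aggregates taxa and reports coverage", {
    depths <- c(25, 45, 100, 125, 150)
    prof <- rbind(s1 = c(0.02, 0.02, 0.001, 0.001, 0.001),
                  s2 = c(0.03, 0.03, 0.001, 0.001, 0.001),
                  d1 = c(0.001, 0.001, 0.05, 0.001, 0.001))
    colnames(prof) <- depths
    out <- classifyDepthZones(prof)
    tax <- c(s1 = "GenusA", s2 = "GenusA", d1 = "GenusB")
    zc <- zoneComposition(out, tax, prof)
    surf <- zc$composition[zc$composition$zone == "Surface", ]
    expect_identical(surf$taxon, "GenusA")
    expect_equal(surf$abundance, 0.05)  # mean over {25, 45} of 0.02 + 0.03
    ## every profiled SASV retained -> coverage 1 everywhere reported
    expect_true(all(abs(zc$coverage$coverage - 1) < 1e-12))
    ## a zone with no depths in the grid simply yields no rows
    expect_false("Bathypelagic" %in% zc$coverage$zone)
    ## missing taxonomy becomes "Unknown"
    zc2 <- zoneComposition(out, c(s1 = "GenusA"), prof)
    expect_true("Unknown" %in% zc2$composition$taxon)
})
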