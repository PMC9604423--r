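# layout whose window 1 midpoint (50 kb) sits exactly 2 Mb from the
# centromere, and whose window 21 midpoint sits on it
.profileLayout <- GenomeLayout("chr1", 4.1e6, 2.05e6, windowSize = 1e5)

test_that("recombination profile follows the suppression formula", {
    par <- defaultParams(baseRate = 1e-6, sigmaCentromere = 2e6, noiseSd = 0)
    prof <- simulateRecombinationProfile(.profileLayout, par)
    rate <- prof$rate
    # window centered on the centromere midpoint: suppression forces 0
    expect_equal(rate[21], 0)
    # d = 2e6, sigma = 2e6: base * (1 - exp(-0.5))
    expect_equal(rate[1], 1e-6 * (1 - exp(-0.5)), tolerance = 1e-12)
    expect_true(all(rate >= 0))

    # far from the centromere the rate approaches the base rate
    far <- GenomeLayout("chr1", 1e8, 1e3 + 1, windowSize = 1e5)
    pf <- simulateRecombinationProfile(far, par)
    expect_equal(tail(pf$rate, 1), 1e-6, tolerance = 1e-9)

    expect_error(defaultParams(sigmaCentromere = -1), "must be > 0")
})

test_that("annotation intensities are monotone in centromere distance", {
    par <- defaultParams()
    gInt <- methRecomb:::.featureIntensity(par, "gene", c(0, 15e6))
    expect_lt(gInt[1], gInt[2])      # genes scarce at the centromere
    for (fc in c("transposon", "retrotransposon")) {
        tInt <- methRecomb:::.featureIntensity(par, fc, c(0, 15e6))
        expect_gt(tInt[1], tInt[2])  # TEs dense at the centromere
    }
    lay <- defaultLayout(nChrom = 2, chromLength = 3e6, seed = 2)
    f1 <- simulateAnnotations(lay, par, 9L)
    f2 <- simulateAnnotations(lay, par, 9L)
    expect_identical(as.data.frame(f1), as.data.frame(f2))  # same seed
    expect_true(all(start(f1) >= 1))
    expect_true(all(end(f1) <= lay@chromLengths[as.character(seqnames(f1))]))
})

test_that("same seed reproduces methylation calls, different seeds differ", {
    lay <- defaultLayout(nChrom = 1, chromLength = 2e6, seed = 4)
    par <- defaultParams()
    a <- simulateVariety(lay, par, 3L)
    b <- simulateVariety(lay, par, 3L)
    expect_identical(as.data.frame(a$records), as.data.frame(b$records))
    expect_identical(a$recombMap$rate, b$recombMap$rate)
    c_ <- simulateVariety(lay, par, 4L)
    expect_false(identical(as.data.frame(a$records),
                           as.data.frame(c_$records)))
})

test_that("degenerate methylation probabilities hit the threshold contract", {
    lay <- GenomeLayout("chr1", 5e5, 2.5e5, windowSize = 1e5)
    par <- defaultParams(pMethHigh = 1.0, pMethLow = 0.0, noiseSd = 0)
    sim <- simulateVariety(lay, par, 2L)
    lev <- methylationLevel(sim$records)
    expect_true(all(lev[sim$records$designed] == 1.0))
    expect_true(all(lev[!sim$records$designed] == 0.0))
    kept <- selectMethylated(sim$records)
    expect_identical(sort(start(kept)),
                     sort(start(sim$records[sim$records$designed])))
})

test_that("per-window CHH counts match the designed expectation", {
    # 200 replicate windows at low density; Monte-Carlo calibration check
    lay <- GenomeLayout("chr1", 2e7, 1e7, windowSize = 1e5)
    par <- defaultParams(baselineDensity = c(CG = 5, CHG = 5, CHH = 20),
                         backgroundDensity = 5, noiseSd = 0,
                         methDispersion = 0)
    prof <- simulateRecombinationProfile(lay, par, 1L)
    empty <- GRanges(feature_class = character())
    sim <- simulateMethylationCalls(lay, empty, prof, par, 12L)
    mu <- methRecomb:::.expectedMethylationDensity(lay, par, prof$rate)
    chh <- sim$records[sim$records$context == "CHH" & sim$records$designed]
    wins <- tileWindows(lay@chromLengths, lay@windowSize)
    counts <- countOverlaps(wins, chh, ignore.strand = TRUE)
    se <- sqrt(sum(mu[, "CHH"])) / length(counts)
    expect_lt(abs(mean(counts) - mean(mu[, "CHH"])), 3 * se)
})

test_that("emitted contexts are literally true in the emitted genome", {
    lay <- GenomeLayout("chrS", 1e5, 5e4, windowSize = 1e4)
    sim <- simulateVariety(lay, defaultParams(), 6L, emitSequence = TRUE)
    r <- sim$records
    expect_gt(sum(as.character(strand(r)) == "-"), 0)  # both strands present
    derived <- classifyContext(sim$genome, as.character(seqnames(r)),
                               start(r), as.character(strand(r)))
    expect_identical(derived, r$context)
})

test_that("features outside the layout are rejected", {
    lay <- GenomeLayout("chr1", 5e5, 2.5e5, windowSize = 1e5)
    par <- defaultParams()
    prof <- simulateRecombinationProfile(lay, par, 1L)
    bad <- GRanges("chr1", IRanges(4.9e5, 6e5), feature_class = "gene")
    expect_error(simulateMethylationCalls(lay, bad, prof, par, 1L),
                 "outside layout")
})

test_that("fixture sets round-trip and echo their parameters exactly", {
    outdir <- file.path(tempfile(), "fix")
    lay <- defaultLayout(nChrom = 2, chromLength = 1e6, seed = 5)
    par <- defaultParams()
    res <- writeFixtureSet(outdir, lay, par, writeFasta = TRUE)
    vA <- res$manifests$varietyA

    # re-parsed CX report has the generator's record count
    records <- readCytosineReport(vA$cx_report)
    expect_equal(length(records), vA$n_records)

    # annotations round-trip with classes intact
    feats <- readAnnotations(vA$annotations)
    expect_true(all(feats$feature_class %in%
                    c("gene", "transposon", "retrotransposon")))
    expect_gt(length(feats), 0)

    # recombination map and centromeres round-trip
    map <- readRecombinationMap(vA$recomb_map)
    expect_equal(length(map), 20L)
    cen <- readCentromereTable(vA$centromeres)
    expect_equal(cen, lay@centromeres)

    # the two varieties differ
    expect_false(identical(tools::md5sum(vA$cx_report)[[1]],
                           tools::md5sum(res$manifests$varietyB$cx_report)[[1]]))

    # truth JSON echoes the parameters bit-exactly
    truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                                 simplifyVector = TRUE)
    echo <- paramsToList(par)
    for (nm in names(echo)) {
        expect_equal(unlist(truth$params[[nm]]), unlist(echo[[nm]]),
                     ignore_attr = TRUE)
    }
    # rerunning with the same seeds reproduces byte-identical files
    outdir2 <- file.path(tempfile(), "fix2")
    writeFixtureSet(outdir2, lay, par, writeFasta = TRUE)
    for (f in c("cx_report.txt", "annotations.gff3", "recomb_map.tsv",
                "centromeres.tsv", "genome.fa")) {
        expect_identical(
            tools::md5sum(file.path(outdir, "varietyA", f))[[1]],
            tools::md5sum(file.path(outdir2, "varietyA", f))[[1]])
    }
})
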