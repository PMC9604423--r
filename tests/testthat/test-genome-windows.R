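test_that("tiling cuts chromosomes into contiguous windows", {
    w <- tileWindows(c(chr1 = 250000))
    expect_equal(start(w) - 1L, c(0L, 100000L, 200000L))
    expect_equal(end(w), c(100000L, 200000L, 250000L))
    expect_equal(w$index, 0:2)

    expect_equal(end(tileWindows(c(c1 = 100000))), 100000L)
    expect_length(tileWindows(c(c1 = 100000)), 1L)
    w2 <- tileWindows(c(c1 = 99999))
    expect_length(w2, 1L)
    expect_equal(end(w2), 99999L)

    expect_error(tileWindows(c(c1 = 0)), "zero-length")
})

test_that("1-based record positions map to windows at the boundary", {
    w <- tileWindows(c(chr1 = 300000))
    r <- function(p) cytosineRecords("chr1", p, "+", 5L, 0L, "CHH", "CAT")
    m <- countMethylatedByWindow(r(100000), w)
    expect_equal(m[, "m_CHH"], c(1L, 0L, 0L))   # pos 100000 -> index 0
    m <- countMethylatedByWindow(r(100001), w)
    expect_equal(m[, "m_CHH"], c(0L, 1L, 0L))   # pos 100001 -> index 1
    expect_error(countMethylatedByWindow(r(300001), w),
                 "beyond chromosome end.*chr1:300001")
})

test_that("counting operations match brute-force oracles on random toys", {
    set.seed(91)
    for (rep in 1:20) {
        nWin <- sample(3:10, 1)
        winSize <- sample(100:300, 1)
        len <- nWin * winSize - sample(0:(winSize - 1), 1)
        chroms <- c(A = len, B = len + winSize)
        wins <- tileWindows(chroms, winSize)
        winDf <- data.frame(chrom = as.character(seqnames(wins)),
                            start0 = start(wins) - 1, end0 = end(wins))

        nRec <- sample(50:1000, 1)
        recDf <- data.frame(
            chrom = sample(names(chroms), nRec, TRUE),
            pos = NA_integer_,
            context = sample(c("CG", "CHG", "CHH"), nRec, TRUE),
            stringsAsFactors = FALSE)
        recDf$pos <- ceiling(runif(nRec) * chroms[recDf$chrom])
        recs <- cytosineRecords(recDf$chrom, recDf$pos, "+", 5L, 0L,
                                recDf$context, "CTA")

        got <- countMethylatedByWindow(recs, wins)
        want <- oracleMethCounts(recDf, winDf)
        expect_equal(got[, "m_CG"], unname(want[, "CG"]))
        expect_equal(got[, "m_CHG"], unname(want[, "CHG"]))
        expect_equal(got[, "m_CHH"], unname(want[, "CHH"]))
        # conservation: every record lands in exactly one window
        expect_equal(sum(got[, "m_all"]), nRec)

        nFeat <- sample(20:200, 1)
        fChrom <- sample(names(chroms), nFeat, TRUE)
        fStart0 <- floor(runif(nFeat) * (chroms[fChrom] - 50))
        fLen <- sample(5:400, nFeat, TRUE)
        fEnd0 <- pmin(fStart0 + fLen, chroms[fChrom])
        featDf <- data.frame(chrom = fChrom, start0 = fStart0, end0 = fEnd0)
        feats <- GRanges(fChrom, IRanges(fStart0 + 1, fEnd0),
                         feature_class = sample(c("gene", "transposon",
                                                  "retrotransposon"),
                                                nFeat, TRUE))
        gotF <- countFeaturesByWindow(feats, wins)
        expect_equal(rowSums(gotF), oracleFeatureCounts(featDf, winDf),
                     ignore_attr = TRUE)
        expect_equal(sum(gotF), nFeat)   # midpoint rule counts each once

        for (fc in c("gene", "transposon", "retrotransposon")) {
            sel <- feats$feature_class == fc
            gotIn <- methylatedWithinFeatures(recs, feats, fc)
            wantKeep <- oracleInFeature(recDf, featDf[sel, , drop = FALSE])
            expect_equal(start(gotIn), recDf$pos[wantKeep])
        }
    }
})

test_that("midpoint rule assigns boundary-spanning features once", {
    w <- tileWindows(c(chr1 = 400000))
    f <- GRanges("chr1", IRanges(150001, 250000), feature_class = "gene")
    cnt <- countFeaturesByWindow(f, w)   # [150000,250000) -> mid 200000
    expect_equal(cnt[, "gene_n"], c(0L, 0L, 1L, 0L))
    f2 <- GRanges("chr1", IRanges(110001, 120000), feature_class = "gene")
    expect_equal(countFeaturesByWindow(f2, w)[, "gene_n"], c(0L, 1L, 0L, 0L))
    expect_error(countFeaturesByWindow(f, w, rule = "overlap"),
                 "unknown feature-counting rule")
})

test_that("in-feature membership is containment, counted once", {
    feats <- GRanges("c", IRanges(c(1, 1), c(100, 80)),
                     feature_class = "gene")   # two overlapping genes
    r <- cytosineRecords("c", c(50, 150), "+", 5L, 0L, "CG", "CGA")
    kept <- methylatedWithinFeatures(r, feats, "gene")
    expect_equal(start(kept), 50L)   # pos 50 kept once, pos 150 dropped
})

test_that("centromere-region labelling intersects the flank interval", {
    w <- tileWindows(c(chr1 = 3000000))
    lab <- labelRegions(w, c(chr1 = 1500000), flank = 0)
    expect_equal(sum(lab$region_label == "centromere_region"), 1L)
    expect_equal(which(lab$region_label == "centromere_region"), 15L)

    lab <- labelRegions(w, c(chr1 = 1500000), flank = 3e6)
    expect_true(all(lab$region_label == "centromere_region"))

    lab <- labelRegions(w, c(chr1 = 1550000), flank = 200000)
    cen <- which(lab$region_label == "centromere_region")
    expect_equal(start(lab)[cen] - 1L, seq(1300000L, 1700000L, by = 100000L))
    # labels partition the windows
    expect_equal(sum(lab$region_label == "arm") + length(cen), length(w))

    expect_error(labelRegions(w, c(chr1 = 5e6), flank = 0),
                 "midpoint outside")
})

test_that("the assembled table satisfies its count identities", {
    lay <- defaultLayout(nChrom = 2, chromLength = 2e6, seed = 3)
    par <- defaultParams()
    sim <- simulateVariety(lay, par, 5L)
    wft <- buildWindowFeatureTable(sim$records, sim$features, sim$recombMap,
                                   sim$centromeres,
                                   chromLengths = lay@chromLengths,
                                   flank = 5e5)
    d <- windowData(wft)
    expect_equal(d$m_all, d$m_CG + d$m_CHG + d$m_CHH)
    expect_true(all(d$m_in_gene <= d$m_all))
    expect_true(all(d$m_in_te <= d$m_all))
    # conservation against the independent filter count
    kept <- selectMethylated(sim$records)
    expect_equal(sum(d$m_all), length(kept))
    tab <- table(kept$context)
    expect_equal(sum(d$m_CHH), unname(tab[["CHH"]]))
    # region labels partition
    expect_equal(sum(d$region_label == "arm") +
                 sum(d$region_label == "centromere_region"), nrow(d))

    # misaligned recombination map is rejected
    shifted <- suppressWarnings(GenomicRanges::shift(sim$recombMap, 1))
    expect_error(
        buildWindowFeatureTable(sim$records, sim$features, shifted,
                                sim$centromeres,
                                chromLengths = lay@chromLengths),
        "not aligned")
})
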