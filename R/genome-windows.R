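.FEATURE_CLASSES <- c("gene", "transposon", "retrotransposon")

#' Tile chromosomes into fixed windows
#'
#' Each chromosome is cut into `ceiling(length / windowSize)` contiguous,
#' non-overlapping windows; the last window is truncated at the chromosome
#' end. A 1-based position p belongs to the window with 0-based start
#' `floor((p - 1) / windowSize) * windowSize`.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param windowSize window width in bp (default 100 kb).
#' @return a [GenomicRanges::GRanges] of windows with metadata columns
#'   `index` (0-based ordinal within chromosome) and `region_label`
#'   (initialised to `"arm"`).
#' @examples
#' tileWindows(c(chr1 = 250000))
#' @export
tileWindows <- function(chromLengths, windowSize = 1e5) {
    stopifnot(windowSize > 0)
    if (any(chromLengths <= 0))
        stop("zero-length chromosome: ",
             paste(names(chromLengths)[chromLengths <= 0], collapse = ", "))
    si <- Seqinfo(names(chromLengths), seqlengths = as.integer(chromLengths))
    parts <- lapply(names(chromLengths), function(ch) {
        len <- chromLengths[[ch]]
        starts <- seq(0, len - 1, by = windowSize)
        GRanges(ch, IRanges(starts + 1, pmin(starts + windowSize, len)),
                index = seq_along(starts) - 1L, seqinfo = si)
    })
    w <- do.call(c, parts)
    mcols(w)$region_label <- "arm"
    w
}

#' Count highly methylated cytosines per window and context
#'
#' @param records filtered cytosine records (output of
#'   [selectMethylated()]); chromosomes must be a subset of the windows'.
#' @param windows tiling from [tileWindows()].
#' @return integer matrix with one row per window and columns `m_CG`,
#'   `m_CHG`, `m_CHH`, `m_all`. Every record is counted in exactly one
#'   window; a record beyond its chromosome end is an error naming it.
#' @export
countMethylatedByWindow <- function(records, windows) {
    chroms <- seqlevels(windows)
    rc <- as.character(seqnames(records))
    if (length(records) && !all(rc %in% chroms))
        stop("records on chromosomes absent from the windows: ",
             paste(unique(setdiff(rc, chroms)), collapse = ", "))
    lens <- setNames(end(windows)[cumsum(runLength(seqnames(windows)))],
                     runValue(seqnames(windows)))
    if (length(records)) {
        beyond <- start(records) > lens[rc] | start(records) < 1
        if (any(beyond)) {
            i <- which(beyond)[1]
            stop("record beyond chromosome end: ", rc[i], ":",
                 start(records)[i])
        }
    }
    out <- matrix(0L, nrow = length(windows), ncol = 4,
                  dimnames = list(NULL, c("m_CG", "m_CHG", "m_CHH", "m_all")))
    for (ctx in .CONTEXTS) {
        sub <- records[mcols(records)$context == ctx]
        out[, paste0("m_", ctx)] <-
            countOverlaps(windows, sub, ignore.strand = TRUE)
    }
    out[, "m_all"] <- out[, "m_CG"] + out[, "m_CHG"] + out[, "m_CHH"]
    out
}

#' Count annotation features per window
#'
#' With the default midpoint rule a feature occupying 0-based half-open
#' interval \[s, e) is assigned to the single window containing
#' `floor((s + e) / 2)`, so every feature is counted exactly once even when
#' it spans a window boundary.
#'
#' @param features a `GRanges` with metadata column `feature_class`
#'   (`gene`, `transposon` or `retrotransposon`).
#' @param windows tiling from [tileWindows()].
#' @param rule assignment rule; only `"midpoint"` is implemented.
#' @return integer matrix, one row per window, columns `gene_n`, `te_n`,
#'   `retro_n`.
#' @export
countFeaturesByWindow <- function(features, windows, rule = "midpoint") {
    if (!identical(rule, "midpoint"))
        stop("unknown feature-counting rule: ", rule)
    cls <- mcols(features)$feature_class
    if (length(features) && (is.null(cls) || !all(cls %in% .FEATURE_CLASSES)))
        stop("features must carry feature_class in {",
             paste(.FEATURE_CLASSES, collapse = ", "), "}")
    # 0-based midpoint of [start-1, end): floor((start - 1 + end) / 2),
    # expressed back in 1-based coordinates for overlap with the windows
    mid0 <- floor((start(features) - 1 + end(features)) / 2)
    midGr <- GRanges(seqnames(features), IRanges(mid0 + 1, width = 1L))
    out <- matrix(0L, nrow = length(windows), ncol = 3,
                  dimnames = list(NULL, c("gene_n", "te_n", "retro_n")))
    colFor <- c(gene = "gene_n", transposon = "te_n",
                retrotransposon = "retro_n")
    for (fc in .FEATURE_CLASSES) {
        sub <- midGr[cls == fc]
        out[, colFor[[fc]]] <- countOverlaps(windows, sub,
                                             ignore.strand = TRUE)
    }
    out
}

#' Restrict methylated cytosines to those inside annotation features
#'
#' Membership, not multiplicity: a record inside two overlapping features of
#' the class is kept once. Strand is ignored -- a cytosine on either strand
#' inside a feature interval counts.
#'
#' @param records filtered cytosine records.
#' @param features annotation `GRanges` with `feature_class`.
#' @param featureClass class to intersect with (`gene`, `transposon`,
#'   `retrotransposon`).
#' @return the subset of `records` lying within at least one feature of the
#'   class.
#' @export
methylatedWithinFeatures <- function(records, features, featureClass) {
    featureClass <- match.arg(featureClass, .FEATURE_CLASSES)
    sub <- features[mcols(features)$feature_class == featureClass]
    keep <- IRanges::overlapsAny(records, sub, ignore.strand = TRUE)
    records[keep]
}

#' Label centromere-region windows
#'
#' Windows whose interval intersects `[midpoint - flank, midpoint + flank]`
#' are labelled `centromere_region`; all others `arm`. The labels partition
#' the windows.
#'
#' @param windows tiling from [tileWindows()].
#' @param centromeres named numeric vector of centromere midpoints (bp),
#'   one per chromosome present in `windows`.
#' @param flank half-width of the centromere region in bp (default 2 Mb).
#' @return `windows` with `region_label` filled in.
#' @export
labelRegions <- function(windows, centromeres, flank = 2e6) {
    stopifnot(flank >= 0)
    chroms <- seqlevels(windows)
    if (!all(chroms %in% names(centromeres)))
        stop("missing centromere midpoint for: ",
             paste(setdiff(chroms, names(centromeres)), collapse = ", "))
    lens <- seqlengths(windows)
    mids <- centromeres[chroms]
    if (any(mids < 1 | mids > lens[chroms]))
        stop("centromere midpoint outside chromosome: ",
             paste(chroms[mids < 1 | mids > lens[chroms]], collapse = ", "))
    cenGr <- GRanges(chroms,
                     IRanges(pmax(1, mids - flank),
                             pmin(as.numeric(lens[chroms]), mids + flank)))
    inCen <- IRanges::overlapsAny(windows, cenGr, ignore.strand = TRUE)
    mcols(windows)$region_label <- ifelse(inCen, "centromere_region", "arm")
    windows
}

#' Assemble the per-window feature table
#'
#' Runs the windowed counting stage end to end: filter cytosine records at
#' the methylation-level threshold, tile the genome, count methylated
#' cytosines per window and context, count features per window (midpoint
#' rule), count methylated cytosines inside each feature class, label
#' centromere-region windows, and join the recombination rate.
#'
#' @param records cytosine records (unfiltered; the threshold is applied
#'   here).
#' @param features annotation `GRanges` with `feature_class` (may be empty).
#' @param recombMap `GRanges` of recombination windows with metadata column
#'   `rate` (cM/bp), aligned to the same tiling.
#' @param centromeres named numeric vector of centromere midpoints.
#' @param chromLengths named chromosome lengths; defaults to the extent of
#'   `recombMap`.
#' @param windowSize window width in bp.
#' @param levelThreshold,minCoverage filtering as in [selectMethylated()].
#' @param flank centromere-region half-width in bp.
#' @return a [WindowFeatureTable-class].
#' @export
buildWindowFeatureTable <- function(records, features, recombMap,
                                    centromeres, chromLengths = NULL,
                                    windowSize = 1e5, levelThreshold = 0.75,
                                    minCoverage = 1L, flank = 2e6) {
    if (is.null(chromLengths)) {
        chromLengths <- vapply(split(end(recombMap), as.character(
            seqnames(recombMap))), max, numeric(1))
    }
    windows <- tileWindows(chromLengths, windowSize)
    windows <- labelRegions(windows, centromeres, flank)
    rc <- unique(as.character(seqnames(recombMap)))
    offenders <- c(setdiff(rc, seqlevels(windows)),
                   setdiff(seqlevels(windows), rc))
    if (length(offenders))
        stop("chromosome name mismatch between recombination map and ",
             "windows: ", paste(offenders, collapse = ", "))
    hits <- findOverlaps(windows, recombMap, type = "equal")
    if (length(hits) != length(windows))
        stop("recombination map is not aligned to the ", windowSize,
             "-bp tiling (", length(hits), " of ", length(windows),
             " windows matched)")
    rate <- rep(NA_real_, length(windows))
    rate[S4Vectors::queryHits(hits)] <-
        mcols(recombMap)$rate[S4Vectors::subjectHits(hits)]

    filtered <- selectMethylated(records, levelThreshold, minCoverage)
    m <- countMethylatedByWindow(filtered, windows)
    f <- countFeaturesByWindow(features, windows)
    inFeat <- vapply(.FEATURE_CLASSES, function(fc) {
        sub <- methylatedWithinFeatures(filtered, features, fc)
        countMethylatedByWindow(sub, windows)[, "m_all"]
    }, integer(length(windows)))
    d <- DataFrame(as.data.frame(m), as.data.frame(f),
                   m_in_gene = inFeat[, "gene"],
                   m_in_te = inFeat[, "transposon"],
                   m_in_retro = inFeat[, "retrotransposon"],
                   recomb_rate = rate)
    new("WindowFeatureTable", windows = windows, data = d,
        windowSize = as.numeric(windowSize))
}
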