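#' @rdname simulateRecombinationProfile
#' @keywords internal
.windowGeometry <- function(layout) {
    w <- tileWindows(layout@chromLengths, layout@windowSize)
    chrom <- as.character(seqnames(w))
    mid <- (start(w) - 1 + end(w)) / 2
    d <- unname(abs(mid - layout@centromeres[chrom]))
    list(windows = w, chrom = chrom, mid = mid, d = d)
}

#' Simulate a centromere-suppressed recombination profile
#'
#' The per-window recombination rate is
#' `base * (1 - exp(-d^2 / (2 * sigma^2))) * max(0, 1 + eps)`, where `d` is
#' the distance from the window midpoint to the centromere midpoint and
#' `eps` is Gaussian noise: recombination vanishes at the centromere and
#' approaches the distal base rate on the arms.
#'
#' @param layout a [GenomeLayout-class].
#' @param params a [SimulationParams-class].
#' @param seed integer seed (default `params@seed`).
#' @return the tiling `GRanges` with metadata columns `index`,
#'   `region_label` and `rate` (cM/bp, all >= 0).
#' @export
simulateRecombinationProfile <- function(layout, params,
                                         seed = params@seed) {
    validObject(layout); validObject(params)
    if (params@sigmaCentromere <= 0)
        stop("sigmaCentromere must be positive")
    g <- .windowGeometry(layout)
    suppression <- 1 - exp(-g$d^2 / (2 * params@sigmaCentromere^2))
    set.seed(seed)
    noise <- pmax(0, 1 + rnorm(length(g$d), 0, params@noiseSd))
    w <- g$windows
    mcols(w)$rate <- params@baseRate * suppression * noise
    w
}

# window-level feature intensity (expected features per window); genes rise
# with distance from the centromere, TE/retro fall
.featureIntensity <- function(params, featureClass, d) {
    s <- exp(-d^2 / (2 * params@sigmaCentromere^2))
    dens <- params@featureDensity[[featureClass]]
    if (featureClass == "gene") dens * (0.2 + 0.8 * (1 - s))
    else dens * (0.2 + 0.8 * s)
}

#' Simulate gene / transposon / retrotransposon annotations
#'
#' Features are drawn from an inhomogeneous Poisson process over the
#' windows: gene intensity increases with distance from the centromere,
#' transposon and retrotransposon intensity decreases. Lengths are
#' exponential around the class mean (floored at 200 bp) and intervals are
#' clipped to the chromosome.
#'
#' @inheritParams simulateRecombinationProfile
#' @return a `GRanges` with metadata column `feature_class`.
#' @export
simulateAnnotations <- function(layout, params, seed = params@seed) {
    validObject(layout); validObject(params)
    g <- .windowGeometry(layout)
    set.seed(seed)
    parts <- list()
    for (fc in .FEATURE_CLASSES) {
        mu <- .featureIntensity(params, fc, g$d)
        n <- rpois(length(mu), mu)
        wi <- rep(seq_along(n), n)
        if (!length(wi)) next
        s0 <- start(g$windows)[wi] - 1
        e0 <- end(g$windows)[wi]
        pos <- floor(runif(length(wi), s0, e0))
        len <- pmax(200, round(stats::rexp(length(wi),
                                           1 / params@featureLength[[fc]])))
        chrom <- g$chrom[wi]
        chromEnd <- layout@chromLengths[chrom]
        fEnd <- pmin(pos + len, chromEnd)
        parts[[fc]] <- data.frame(
            chrom = chrom, start = pos + 1, end = fEnd,
            feature_class = fc,
            strand = sample(c("+", "-"), length(wi), replace = TRUE),
            stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, parts)
    if (is.null(df))
        return(GRanges(feature_class = character()))
    o <- order(factor(df$chrom, levels = layout@chromNames), df$start)
    df <- df[o, ]
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                  feature_class = df$feature_class)
    seqlevels(gr) <- layout@chromNames
    seqlengths(gr) <- layout@chromLengths
    mcols(gr)$feature_id <- sprintf("%s_%05d",
                                    substr(df$feature_class, 1, 4),
                                    seq_along(gr))
    gr
}

# designed-methylated expectation per window per context (before feature
# extras and hard-core position thinning)
.expectedMethylationDensity <- function(layout, params, rate) {
    g <- .windowGeometry(layout)
    h <- exp(-g$d^2 / (2 * params@sigmaHeterochromatin^2))
    b <- params@baselineDensity
    cbind(
        CG = b[["CG"]] * (1 + params@cgChgCoupling * h),
        CHG = b[["CHG"]] * (1 + params@cgChgCoupling * h),
        CHH = b[["CHH"]] * (1 + params@chhCoupling * rate / params@baseRate)
    )
}

# drop later members of position pairs closer than `gap`, iteratively;
# guarantees the written trinucleotide triplets never overlap
.thinPositions <- function(pos, gap = 5L) {
    keep <- seq_along(pos)
    repeat {
        bad <- which(diff(pos[keep]) < gap) + 1L
        if (!length(bad)) break
        keep <- keep[-bad]
    }
    keep
}

.TRI_H <- c("A", "T")  # emitted H bases; subset of {A, C, T}, avoids stray Cs

.sampleTrinucleotide <- function(context) {
    n <- length(context)
    h1 <- sample(.TRI_H, n, replace = TRUE)
    h2 <- sample(.TRI_H, n, replace = TRUE)
    ifelse(context == "CG", paste0("CG", h1),
        ifelse(context == "CHG", paste0("C", h1, "G"),
               paste0("C", h1, h2)))
}

#' Simulate per-cytosine methylation calls (and optionally the genome)
#'
#' Places cytosines per context with window-level expected counts: CG and
#' CHG densities rise toward the centromere (broad heterochromatin domain)
#' and inside transposon/retrotransposon intervals; CHH density is an
#' affine increasing function of the window's recombination rate, plus
#' CHH islands around gene boundaries. Background cytosines with a low
#' methylation probability are added in all contexts. Each cytosine gets
#' Poisson coverage (floored at 1 read) and a binomial methylated-read
#' count with probability `pMethHigh` (designed) or `pMethLow` (background).
#'
#' Positions are spaced at least 5 bp apart so that, when a genome is
#' emitted, every record's trinucleotide can be written literally into the
#' sequence; the emitted context is then exactly what [classifyContext()]
#' recovers at that position and strand.
#'
#' @inheritParams simulateRecombinationProfile
#' @param features annotations from [simulateAnnotations()] (must lie within
#'   the layout).
#' @param recombProfile output of [simulateRecombinationProfile()] on the
#'   same layout.
#' @param emitSequence also build the genome as a
#'   [Biostrings::DNAStringSet] (A background with the record trinucleotides
#'   written in); intended for desk-scale layouts.
#' @return list with `records` (cytosine `GRanges` carrying `n_meth`,
#'   `n_unmeth`, `context`, `trinucleotide`, `designed`) and `genome`
#'   (`DNAStringSet` or `NULL`).
#' @export
simulateMethylationCalls <- function(layout, features, recombProfile,
                                     params, seed = params@seed,
                                     emitSequence = FALSE) {
    validObject(layout); validObject(params)
    g <- .windowGeometry(layout)
    if (length(recombProfile) != length(g$windows))
        stop("recombination profile is not defined on the layout's windows")
    rate <- mcols(recombProfile)$rate
    if (length(features)) {
        fc <- as.character(seqnames(features))
        if (!all(fc %in% layout@chromNames) ||
            any(end(features) > layout@chromLengths[fc]) ||
            any(start(features) < 1))
            stop("features outside layout")
    }
    mu <- .expectedMethylationDensity(layout, params, rate)

    set.seed(seed)
    parts <- list()
    emit <- function(chrom, pos, context, designed)
        data.frame(chrom = chrom, pos = pos, context = context,
                   designed = designed, stringsAsFactors = FALSE)
    # designed, window-driven (gamma-overdispersed Poisson when
    # methDispersion > 0)
    for (ctx in .CONTEXTS) {
        muc <- mu[, ctx]
        if (params@methDispersion > 0) {
            shp <- 1 / params@methDispersion^2
            muc <- muc * stats::rgamma(length(muc), shape = shp,
                                       rate = shp)
        }
        n <- rpois(length(muc), muc)
        wi <- rep(seq_along(n), n)
        if (!length(wi)) next
        pos <- floor(runif(length(wi), start(g$windows)[wi] - 1,
                           end(g$windows)[wi])) + 1
        parts[[paste0("w_", ctx)]] <- emit(g$chrom[wi], pos, ctx, TRUE)
    }
    # designed, inside TE/retro intervals (CG/CHG enrichment)
    te <- features[mcols(features)$feature_class %in%
                   c("transposon", "retrotransposon")]
    if (length(te)) {
        for (ctx in c("CG", "CHG")) {
            n <- rpois(length(te), width(te) * params@teMethRate[[ctx]])
            fi <- rep(seq_along(n), n)
            if (!length(fi)) next
            pos <- floor(runif(length(fi), start(te)[fi] - 1,
                               end(te)[fi])) + 1
            parts[[paste0("te_", ctx)]] <-
                emit(as.character(seqnames(te))[fi], pos, ctx, TRUE)
        }
    }
    # designed CHH islands at gene boundaries
    genes <- features[mcols(features)$feature_class == "gene"]
    if (length(genes)) {
        bchrom <- rep(as.character(seqnames(genes)), 2)
        bpos <- c(start(genes), end(genes))
        n <- rpois(length(bpos), params@chhIslandMean)
        bi <- rep(seq_along(n), n)
        if (length(bi)) {
            w <- params@chhIslandWidth
            pos <- floor(runif(length(bi), bpos[bi] - w, bpos[bi] + w))
            lim <- layout@chromLengths[bchrom[bi]]
            ok <- pos >= 1 & pos <= lim
            parts[["island_CHH"]] <- emit(bchrom[bi][ok], pos[ok],
                                          "CHH", TRUE)
        }
    }
    # background, lowly methylated
    for (ctx in .CONTEXTS) {
        n <- rpois(nrow(mu), params@backgroundDensity)
        wi <- rep(seq_along(n), n)
        if (!length(wi)) next
        pos <- floor(runif(length(wi), start(g$windows)[wi] - 1,
                           end(g$windows)[wi])) + 1
        parts[[paste0("bg_", ctx)]] <- emit(g$chrom[wi], pos, ctx, FALSE)
    }
    df <- do.call(rbind, parts)
    df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
    # order along the genome and enforce the 5-bp hard core
    o <- order(factor(df$chrom, levels = layout@chromNames), df$pos)
    df <- df[o, ]
    lim <- layout@chromLengths[df$chrom]
    df <- df[df$pos >= 3 & df$pos <= lim - 2, ]
    grp <- factor(df$chrom, levels = layout@chromNames)
    keep <- unlist(lapply(split(seq_len(nrow(df)), grp), function(i)
        i[.thinPositions(df$pos[i])]), use.names = FALSE)
    df <- df[sort(keep), ]

    cov <- pmax(1L, rpois(nrow(df), params@coverageMean))
    p <- ifelse(df$designed, params@pMethHigh, params@pMethLow)
    nMeth <- rbinom(nrow(df), cov, p)
    tri <- .sampleTrinucleotide(df$context)

    records <- cytosineRecords(df$chrom, df$pos, df$strand, nMeth,
                               cov - nMeth, df$context, tri)
    seqlevels(records) <- layout@chromNames
    seqlengths(records) <- layout@chromLengths
    mcols(records)$designed <- df$designed

    genome <- NULL
    if (emitSequence)
        genome <- .buildGenome(layout, records)
    list(records = records, genome = genome)
}

# A-background genome with each record's trinucleotide written literally at
# its position and strand
.buildGenome <- function(layout, records) {
    seqs <- lapply(layout@chromNames, function(ch) {
        v <- rep("A", layout@chromLengths[[ch]])
        r <- records[seqnames(records) == ch]
        if (length(r)) {
            p <- start(r)
            tri <- matrix(unlist(strsplit(mcols(r)$trinucleotide, "")),
                          ncol = 3, byrow = TRUE)
            plus <- as.character(strand(r)) == "+"
            if (any(plus)) {
                v[p[plus]] <- tri[plus, 1]
                v[p[plus] + 1] <- tri[plus, 2]
                v[p[plus] + 2] <- tri[plus, 3]
            }
            if (any(!plus)) {
                v[p[!plus]] <- .complement[tri[!plus, 1]]
                v[p[!plus] - 1] <- .complement[tri[!plus, 2]]
                v[p[!plus] - 2] <- .complement[tri[!plus, 3]]
            }
        }
        paste(v, collapse = "")
    })
    DNAStringSet(setNames(unlist(seqs), layout@chromNames))
}

#' Simulate one synthetic variety
#'
#' Convenience wrapper generating, from one seed, a coherent dataset:
#' recombination profile, annotations and methylation calls sharing the
#' generative law encoded in `params`. Varieties generated with different
#' seeds emulate independently obtained datasets.
#'
#' @inheritParams simulateRecombinationProfile
#' @param emitSequence passed to [simulateMethylationCalls()].
#' @return list with `records`, `features`, `recombMap` (windows with
#'   `rate`), `centromeres`, `genome` and `truth` (designed correlation
#'   signs, seeds, parameter echo).
#' @export
simulateVariety <- function(layout, params, seed = params@seed,
                            emitSequence = FALSE) {
    prof <- simulateRecombinationProfile(layout, params, seed)
    feats <- simulateAnnotations(layout, params, seed + 1L)
    meth <- simulateMethylationCalls(layout, feats, prof, params,
                                     seed + 2L, emitSequence)
    list(
        records = meth$records,
        features = feats,
        recombMap = prof,
        centromeres = layout@centromeres,
        genome = meth$genome,
        truth = list(
            designed_signs = list(m_CHH = 1, m_CG = -1, m_CHG = -1,
                                  m_all = -1, gene_n = 1, te_n = -1,
                                  retro_n = -1),
            seeds = list(profile = seed, annotations = seed + 1L,
                         methylation = seed + 2L),
            params = paramsToList(params),
            layout = layoutToList(layout)
        )
    )
}

#' @rdname writeFixtureSet
#' @param params a [SimulationParams-class].
#' @export
paramsToList <- function(params) {
    sl <- slotNames("SimulationParams")
    setNames(lapply(sl, function(s) {
        v <- slot(params, s)
        if (is.null(names(v))) v else as.list(v)
    }), sl)
}

#' @rdname writeFixtureSet
#' @param layout a [GenomeLayout-class].
#' @export
layoutToList <- function(layout) {
    list(chromNames = layout@chromNames,
         chromLengths = as.list(layout@chromLengths),
         centromeres = as.list(layout@centromeres),
         windowSize = layout@windowSize)
}

#' Write a paired synthetic fixture set to disk
#'
#' Generates `nVarieties` datasets sharing one generative law but differing
#' in seeds (emulating independently obtained varieties) and writes, per
#' variety: a Bismark-layout cytosine report, GFF3 annotations, a
#' tab-delimited per-window recombination map, a centromere table and
#' (optionally) the genome FASTA; plus one shared `truth.json` echoing the
#' parameters, seeds and designed correlation signs.
#'
#' @param outdir output directory (created if missing).
#' @param layout a [GenomeLayout-class].
#' @param params a [SimulationParams-class].
#' @param nVarieties number of varieties.
#' @param seeds integer seeds, one per variety; defaults to
#'   `params@seed + (0:(nVarieties-1)) * 1000`.
#' @param writeFasta also emit and write the genome FASTA (desk-scale
#'   layouts only).
#' @return invisibly, a list with the per-variety file manifests and the
#'   truth record.
#' @export
writeFixtureSet <- function(outdir, layout = defaultLayout(),
                            params = defaultParams(), nVarieties = 2,
                            seeds = params@seed +
                                (seq_len(nVarieties) - 1L) * 1000L,
                            writeFasta = TRUE) {
    stopifnot(length(seeds) == nVarieties)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    varieties <- sprintf("variety%s", LETTERS[seq_len(nVarieties)])
    manifests <- list()
    for (i in seq_len(nVarieties)) {
        sim <- simulateVariety(layout, params, as.integer(seeds[i]),
                               emitSequence = writeFasta)
        vd <- file.path(outdir, varieties[i])
        dir.create(vd, showWarnings = FALSE)
        files <- list(
            cx_report = file.path(vd, "cx_report.txt"),
            annotations = file.path(vd, "annotations.gff3"),
            recomb_map = file.path(vd, "recomb_map.tsv"),
            centromeres = file.path(vd, "centromeres.tsv")
        )
        writeCytosineReport(sim$records, files$cx_report)
        writeAnnotations(sim$features, files$annotations)
        writeRecombinationMap(sim$recombMap, files$recomb_map)
        writeCentromereTable(sim$centromeres, files$centromeres)
        if (writeFasta) {
            files$genome <- file.path(vd, "genome.fa")
            writeXStringSet(sim$genome, files$genome)
        }
        manifests[[varieties[i]]] <-
            c(files, list(seed = as.integer(seeds[i]),
                          n_records = length(sim$records)))
    }
    truth <- list(
        designed_signs = list(m_CHH = 1, m_CG = -1, m_CHG = -1, m_all = -1,
                              gene_n = 1, te_n = -1, retro_n = -1),
        seeds = as.integer(seeds),
        varieties = varieties,
        params = paramsToList(params),
        layout = layoutToList(layout)
    )
    write_json(truth, file.path(outdir, "truth.json"), auto_unbox = TRUE,
               digits = NA)
    invisible(list(manifests = manifests, truth = truth))
}
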