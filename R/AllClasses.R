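#' Genome layout for simulation and windowing
#'
#' Describes the chromosomes of a (real or simulated) genome: names, lengths,
#' centromere midpoints and the window size used to tile it.
#'
#' @slot chromNames character, chromosome identifiers.
#' @slot chromLengths numeric, chromosome lengths in bp (named by chromosome).
#' @slot centromeres numeric, centromere midpoint in bp per chromosome
#'   (named by chromosome), strictly inside the chromosome.
#' @slot windowSize numeric scalar, tiling window width in bp.
#'
#' @export
setClass("GenomeLayout",
    representation(
        chromNames = "character",
        chromLengths = "numeric",
        centromeres = "numeric",
        windowSize = "numeric"
    )
)

setValidity("GenomeLayout", function(object) {
    msg <- character()
    n <- length(object@chromNames)
    if (n == 0L) msg <- c(msg, "at least one chromosome is required")
    if (length(object@chromLengths) != n || length(object@centromeres) != n)
        msg <- c(msg, "chromLengths and centromeres must match chromNames")
    if (any(object@chromLengths <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
    inside <- object@centromeres > 0 & object@centromeres < object@chromLengths
    if (!all(inside))
        msg <- c(msg, "each centromere midpoint must lie strictly inside its chromosome")
    if (length(object@windowSize) != 1L || object@windowSize <= 0)
        msg <- c(msg, "windowSize must be a positive scalar")
    else if (n > 0L && object@windowSize > min(object@chromLengths))
        msg <- c(msg, "windowSize must not exceed the shortest chromosome")
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeLayout
#'
#' @param chromNames character vector of chromosome identifiers.
#' @param chromLengths numeric vector of lengths (bp), same order.
#' @param centromeres numeric vector of centromere midpoints (bp), same order.
#' @param windowSize window width in bp (default 100 kb).
#' @return A [GenomeLayout-class] object.
#' @examples
#' GenomeLayout("chr1", 3e6, 1.5e6)
#' @export
GenomeLayout <- function(chromNames, chromLengths, centromeres,
                         windowSize = 1e5) {
    chromLengths <- setNames(as.numeric(chromLengths), chromNames)
    centromeres <- setNames(as.numeric(centromeres), chromNames)
    new("GenomeLayout", chromNames = as.character(chromNames),
        chromLengths = chromLengths, centromeres = centromeres,
        windowSize = as.numeric(windowSize))
}

#' Rice-like default genome layout
#'
#' Twelve chromosomes of 30 Mb tiled in 100-kb windows, with centromere
#' midpoints placed in the central third of each chromosome. This is the
#' default scale at which the synthetic generator emulates a rice genome.
#'
#' @param nChrom number of chromosomes.
#' @param chromLength length of every chromosome, bp.
#' @param windowSize tiling window, bp.
#' @param seed integer seed controlling centromere placement.
#' @return A [GenomeLayout-class].
#' @examples
#' defaultLayout(nChrom = 2, chromLength = 2e6)
#' @export
defaultLayout <- function(nChrom = 12, chromLength = 30e6, windowSize = 1e5,
                          seed = 7L) {
    nm <- sprintf("chr%02d", seq_len(nChrom))
    set.seed(seed)
    cen <- runif(nChrom, chromLength / 3, 2 * chromLength / 3)
    GenomeLayout(nm, rep(chromLength, nChrom), round(cen), windowSize)
}

#' Parameters of the synthetic methylation/recombination generator
#'
#' Encodes the generative law shared by simulated varieties: a
#' Gaussian-suppression recombination profile around the centromere,
#' pericentromeric CG/CHG methylated-cytosine enrichment over a broad
#' heterochromatin domain, CHH density coupled affinely to the local
#' recombination rate plus CHH islands at gene boundaries, inhomogeneous
#' Poisson feature placement, and binomial read sampling over Poisson
#' coverage.
#'
#' @slot baseRate numeric, distal recombination rate in cM/bp.
#' @slot sigmaCentromere numeric, width (bp) of the Gaussian recombination
#'   suppression around the centromere midpoint.
#' @slot sigmaHeterochromatin numeric, width (bp) of the pericentromeric
#'   CG/CHG methylation domain (broader than the recombination suppression,
#'   as in pericentromeric heterochromatin).
#' @slot baselineDensity named numeric (CG, CHG, CHH), expected
#'   designed-methylated cytosines per window away from any enrichment.
#' @slot cgChgCoupling numeric > 0, dimensionless amplitude of the
#'   pericentromeric CG/CHG enrichment relative to baseline.
#' @slot chhCoupling numeric > 0, dimensionless CHH-recombination coupling:
#'   CHH density is baseline * (1 + chhCoupling * rate / baseRate).
#' @slot featureDensity named numeric (gene, transposon, retrotransposon),
#'   expected features per window at each class's favoured location.
#' @slot featureLength named numeric, mean feature length (bp) per class.
#' @slot teMethRate named numeric (CG, CHG), extra designed-methylated
#'   cytosines per bp inside transposon/retrotransposon intervals.
#' @slot chhIslandMean numeric, expected extra CHH cytosines per gene
#'   boundary ("CHH islands").
#' @slot chhIslandWidth numeric, half-width (bp) of the CHH island around
#'   each gene boundary.
#' @slot backgroundDensity numeric, lowly methylated cytosines per window
#'   per context.
#' @slot coverageMean numeric, Poisson mean read coverage (floored at 1).
#' @slot pMethHigh,pMethLow numeric in [0,1], within-cytosine methylation
#'   probabilities of designed-methylated and background cytosines;
#'   pMethHigh > 0.75 > pMethLow so the counting threshold separates them.
#' @slot noiseSd numeric, standard deviation of the multiplicative
#'   recombination noise (the window-scale ruggedness of the recombination
#'   landscape).
#' @slot methDispersion numeric >= 0, overdispersion of the per-window
#'   methylation densities: expected counts are multiplied by a mean-1
#'   gamma variate with this coefficient of variation (0 = pure Poisson).
#' @slot seed integer, default random seed.
#'
#' @export
setClass("SimulationParams",
    representation(
        baseRate = "numeric",
        sigmaCentromere = "numeric",
        sigmaHeterochromatin = "numeric",
        baselineDensity = "numeric",
        cgChgCoupling = "numeric",
        chhCoupling = "numeric",
        featureDensity = "numeric",
        featureLength = "numeric",
        teMethRate = "numeric",
        chhIslandMean = "numeric",
        chhIslandWidth = "numeric",
        backgroundDensity = "numeric",
        coverageMean = "numeric",
        pMethHigh = "numeric",
        pMethLow = "numeric",
        noiseSd = "numeric",
        methDispersion = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationParams", function(object) {
    msg <- character()
    pos <- c(baseRate = object@baseRate,
             sigmaCentromere = object@sigmaCentromere,
             sigmaHeterochromatin = object@sigmaHeterochromatin,
             cgChgCoupling = object@cgChgCoupling,
             chhCoupling = object@chhCoupling,
             chhIslandWidth = object@chhIslandWidth,
             coverageMean = object@coverageMean)
    if (any(pos <= 0))
        msg <- c(msg, paste("must be > 0:",
                 paste(names(pos)[pos <= 0], collapse = ", ")))
    if (!identical(sort(names(object@baselineDensity)), c("CG", "CHG", "CHH")))
        msg <- c(msg, "baselineDensity must be named CG, CHG, CHH")
    if (any(object@baselineDensity <= 0) || any(object@featureDensity <= 0))
        msg <- c(msg, "densities must be > 0")
    if (!identical(sort(names(object@featureDensity)),
                   sort(c("gene", "transposon", "retrotransposon"))))
        msg <- c(msg, "featureDensity must be named gene, transposon, retrotransposon")
    p <- c(object@pMethHigh, object@pMethLow)
    if (any(p < 0 | p > 1)) msg <- c(msg, "methylation probabilities must be in [0,1]")
    if (!(object@pMethHigh > 0.75 && object@pMethLow < 0.75))
        msg <- c(msg, "pMethHigh > 0.75 > pMethLow is required")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@methDispersion < 0)
        msg <- c(msg, "methDispersion must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Default generator parameters
#'
#' Densities are desk-scale (a real rice genome carries far more methylated
#' cytosines); they are calibrated to reproduce the qualitative structure of
#' the study system -- correlation signs and centromere stratification -- not
#' absolute methylation magnitudes.
#'
#' @param ... named overrides for any slot of
#'   [SimulationParams-class].
#' @return A [SimulationParams-class] object.
#' @examples
#' defaultParams(noiseSd = 0)
#' @export
defaultParams <- function(...) {
    defaults <- list(
        baseRate = 4e-8,
        sigmaCentromere = 2e6,
        sigmaHeterochromatin = 5e6,
        baselineDensity = c(CG = 60, CHG = 40, CHH = 20),
        cgChgCoupling = 3.5,
        chhCoupling = 1.6,
        featureDensity = c(gene = 8, transposon = 6, retrotransposon = 5),
        featureLength = c(gene = 3000, transposon = 1000,
                          retrotransposon = 5000),
        teMethRate = c(CG = 0.006, CHG = 0.004),
        chhIslandMean = 4,
        chhIslandWidth = 1000,
        backgroundDensity = 40,
        coverageMean = 10,
        pMethHigh = 0.9,
        pMethLow = 0.05,
        noiseSd = 0.5,
        methDispersion = 0.15,
        seed = 1L
    )
    args <- modifyList(defaults, list(...))
    args$seed <- as.integer(args$seed)
    do.call(new, c(list("SimulationParams"), args))
}

#' Per-window feature table
#'
#' Holds, for every genomic window, the counts of highly methylated cytosines
#' (total and per context), annotation feature counts, within-feature
#' methylation counts and the local recombination rate, together with the
#' window ranges and their arm / centromere-region labels.
#'
#' @slot windows a [GenomicRanges::GRanges] of the tiling windows, with
#'   metadata columns `index` (0-based ordinal within chromosome) and
#'   `region_label` (`"arm"` or `"centromere_region"`).
#' @slot data a [S4Vectors::DataFrame] with one row per window and columns
#'   `m_CG`, `m_CHG`, `m_CHH`, `m_all`, `gene_n`, `te_n`, `retro_n`,
#'   `m_in_gene`, `m_in_te`, `m_in_retro`, `recomb_rate`.
#' @slot windowSize numeric scalar, tiling width in bp.
#'
#' @export
setClass("WindowFeatureTable",
    representation(
        windows = "GRanges",
        data = "DataFrame",
        windowSize = "numeric"
    )
)

.WFT_COUNT_COLS <- c("m_CG", "m_CHG", "m_CHH", "m_all", "gene_n", "te_n",
                     "retro_n", "m_in_gene", "m_in_te", "m_in_retro")
.WFT_COLS <- c(.WFT_COUNT_COLS, "recomb_rate")

setValidity("WindowFeatureTable", function(object) {
    msg <- character()
    if (nrow(object@data) != length(object@windows))
        msg <- c(msg, "data must have one row per window")
    missing <- setdiff(.WFT_COLS, colnames(object@data))
    if (length(missing))
        msg <- c(msg, paste("missing columns:", paste(missing, collapse = ", ")))
    if (!all(c("index", "region_label") %in% colnames(mcols(object@windows))))
        msg <- c(msg, "windows must carry index and region_label")
    if (!length(msg)) {
        d <- object@data
        cnt <- as.matrix(as.data.frame(d[, .WFT_COUNT_COLS]))
        if (any(cnt < 0)) msg <- c(msg, "counts must be >= 0")
        if (any(d$m_all != d$m_CG + d$m_CHG + d$m_CHH))
            msg <- c(msg, "m_all must equal m_CG + m_CHG + m_CHH")
        over <- d$m_in_gene > d$m_all | d$m_in_te > d$m_all |
            d$m_in_retro > d$m_all
        if (any(over))
            msg <- c(msg, "within-feature counts cannot exceed m_all")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "WindowFeatureTable", function(object) {
    chroms <- unique(as.character(seqnames(object@windows)))
    lab <- table(mcols(object@windows)$region_label)
    cat("WindowFeatureTable:", length(object@windows), "windows of",
        format(object@windowSize, big.mark = ","), "bp on",
        length(chroms), "chromosome(s)\n")
    cat("  region labels:",
        paste(sprintf("%s=%d", names(lab), as.integer(lab)), collapse = ", "),
        "\n")
    cat("  variables:", paste(.WFT_COLS, collapse = ", "), "\n")
})

#' @describeIn WindowFeatureTable-class the tiling windows (`GRanges`).
#' @param x a `WindowFeatureTable`.
#' @export
windowRanges <- function(x) {
    stopifnot(is(x, "WindowFeatureTable"))
    x@windows
}

#' @describeIn WindowFeatureTable-class the per-window variables as a
#'   `data.frame` with `chrom`, `window_start` (0-based), `window_end`,
#'   `index` and `region_label` prepended.
#' @export
windowData <- function(x) {
    stopifnot(is(x, "WindowFeatureTable"))
    w <- x@windows
    cbind(
        data.frame(
            chrom = as.character(seqnames(w)),
            window_start = start(w) - 1L,
            window_end = end(w),
            index = mcols(w)$index,
            region_label = mcols(w)$region_label,
            stringsAsFactors = FALSE
        ),
        as.data.frame(x@data)
    )
}
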