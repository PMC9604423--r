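#' Read and write the delimited interchange formats
#'
#' The pipeline's delimited formats are: a per-window recombination map
#' (`chrom`, `window_start` 0-based, `window_end`, `rate_cM_per_bp`), a
#' centromere table (`chrom`, `midpoint_bp`), GFF3 annotations (types `gene`
#' and `transposable_element`, the latter with a `te_class` attribute
#' distinguishing transposons from retrotransposons), the per-window feature
#' table and the correlation report. All are tab-delimited with a header
#' except GFF3.
#'
#' @param path file path.
#' @param gr recombination windows (`GRanges` with `rate`).
#' @name interchange-formats
NULL

#' @rdname interchange-formats
#' @export
writeRecombinationMap <- function(gr, path) {
    fwrite(data.table(
        chrom = as.character(seqnames(gr)),
        window_start = start(gr) - 1L,
        window_end = end(gr),
        rate_cM_per_bp = mcols(gr)$rate
    ), path, sep = "\t")
    invisible(path)
}

#' @rdname interchange-formats
#' @export
readRecombinationMap <- function(path) {
    dt <- fread(path, sep = "\t")
    need <- c("chrom", "window_start", "window_end", "rate_cM_per_bp")
    if (!all(need %in% names(dt)))
        stop("recombination map must have columns: ",
             paste(need, collapse = ", "))
    GRanges(dt$chrom, IRanges(dt$window_start + 1L, dt$window_end),
            rate = dt$rate_cM_per_bp)
}

#' @rdname interchange-formats
#' @param centromeres named numeric vector of midpoints (bp).
#' @export
writeCentromereTable <- function(centromeres, path) {
    fwrite(data.table(chrom = names(centromeres),
                      midpoint_bp = as.numeric(centromeres)),
           path, sep = "\t")
    invisible(path)
}

#' @rdname interchange-formats
#' @export
readCentromereTable <- function(path) {
    dt <- fread(path, sep = "\t")
    setNames(dt$midpoint_bp, dt$chrom)
}

#' @rdname interchange-formats
#' @param features annotation `GRanges` with `feature_class`.
#' @export
writeAnnotations <- function(features, path) {
    gr <- features
    cls <- mcols(gr)$feature_class
    mcols(gr) <- NULL
    mcols(gr)$source <- "methRecomb"
    mcols(gr)$type <- ifelse(cls == "gene", "gene", "transposable_element")
    mcols(gr)$ID <- sprintf("%s_%06d", cls, seq_along(gr))
    mcols(gr)$te_class <- ifelse(cls == "gene", NA_character_, cls)
    export.gff3(gr, path)
    invisible(path)
}

#' @rdname interchange-formats
#' @param typeMap named character vector mapping GFF3 `type` values to
#'   feature classes; `transposable_element` is resolved through the
#'   `te_class` attribute when present.
#' @export
readAnnotations <- function(path,
                            typeMap = c(gene = "gene",
                                        transposon = "transposon",
                                        retrotransposon = "retrotransposon",
                                        transposable_element = "transposon")) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(mcols(gr)$type)
    cls <- unname(typeMap[type])
    tc <- mcols(gr)$te_class
    if (!is.null(tc)) {
        hasTc <- !is.na(tc) & tc %in% .FEATURE_CLASSES
        cls[hasTc] <- tc[hasTc]
    }
    keep <- !is.na(cls)
    gr <- gr[keep]
    mcols(gr) <- NULL
    mcols(gr)$feature_class <- cls[keep]
    gr
}

#' @rdname interchange-formats
#' @param wft a [WindowFeatureTable-class].
#' @export
writeWindowFeatureTable <- function(wft, path) {
    fwrite(as.data.table(windowData(wft)), path, sep = "\t")
    invisible(path)
}

#' @rdname interchange-formats
#' @export
readWindowFeatureTable <- function(path) {
    df <- setDF(fread(path, sep = "\t"))
    lens <- vapply(split(df$window_end, df$chrom), max, numeric(1))
    w <- GRanges(df$chrom, IRanges(df$window_start + 1L, df$window_end),
                 index = df$index, region_label = df$region_label)
    seqlengths(w) <- lens[seqlevels(w)]
    d <- DataFrame(df[, .WFT_COLS])
    ws <- max(df$window_end - df$window_start)
    new("WindowFeatureTable", windows = w, data = d, windowSize = ws)
}

#' @rdname interchange-formats
#' @param report a correlation report (see [correlationReport()]).
#' @param jsonPath optional path for a JSON copy.
#' @export
writeCorrelationReport <- function(report, path, jsonPath = NULL) {
    fwrite(as.data.table(report), path, sep = "\t")
    if (!is.null(jsonPath))
        write_json(report, jsonPath, dataframe = "rows", auto_unbox = TRUE,
                   digits = NA, na = "null")
    invisible(path)
}

#' Heatmap of a correlation report
#'
#' Draws the per-chromosome correlation matrix (chromosomes by variables)
#' for one stratum, mirroring the study-style correlation heatmaps.
#' Requires the `pheatmap` package.
#'
#' @param report output of [correlationReport()].
#' @param stratum stratum to display.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the `pheatmap` object, invisibly.
#' @export
plotCorrelationHeatmap <- function(report, stratum = "whole", ...) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("plotCorrelationHeatmap requires the 'pheatmap' package")
    sub <- report[report$stratum == stratum, ]
    m <- tapply(sub$pearson_r, list(sub$chrom, sub$variable), identity)
    ph <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                             breaks = seq(-1, 1, length.out = 101), ...)
    invisible(ph)
}
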