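#' Pipeline configuration
#'
#' A pipeline run is described by a flat, YAML-serialisable list. Defaults
#' follow the analysis parameters: 100-kb windows, a strict 75%
#' methylation-level threshold, input smoothing `alpha = 0.1`, output
#' smoothing `alpha = 0.3`, a 2-Mb centromere flank, and a CHH-only
#' extra-trees predictor with 100 trees.
#'
#' @param ... named overrides of any default entry. Nested entries:
#'   `paths` (`cx_report`, `annotations`, `recomb_map`, `centromere_table`,
#'   `genome`, `output_dir`), `simulate` (`n_chrom`, `chrom_length`,
#'   `layout_seed`, `n_varieties`, `write_fasta`) and `params` (overrides
#'   for [defaultParams()]).
#' @return the configuration list.
#' @export
defaultPipelineConfig <- function(...) {
    cfg <- list(
        window_size = 1e5,
        level_threshold = 0.75,
        min_coverage = 1,
        input_alpha = 0.1,
        output_alpha = 0.3,
        centromere_flank = 2e6,
        features = "m_CHH",
        algorithm = "extra_trees",
        num_trees = 100,
        model_seed = 42,
        seed = 1,
        dataset_id = "dataset",
        paths = list(output_dir = "methRecomb_out"),
        simulate = list(n_chrom = 12, chrom_length = 30e6, layout_seed = 7,
                        n_varieties = 2, write_fasta = TRUE),
        params = list()
    )
    over <- list(...)
    if (length(over)) cfg <- modifyList(cfg, over)
    cfg
}

#' @rdname defaultPipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("no such config file: ", path)
    defaultPipelineConfig() |> modifyList(read_yaml(path))
}

#' @rdname defaultPipelineConfig
#' @param config a configuration list.
#' @export
writePipelineConfig <- function(config, path) {
    write_yaml(config, path)
    invisible(path)
}

.writeRunSidecar <- function(dir, stage, config, extra = list()) {
    write_json(c(list(stage = stage, config = config), extra),
               file.path(dir, paste0(stage, "_run.json")),
               auto_unbox = TRUE, digits = NA)
}

#' Pipeline stage: simulate a paired fixture set
#'
#' Wraps [writeFixtureSet()] with the layout, parameters and seeds taken
#' from the configuration; writes a sidecar JSON with the resolved
#' configuration and seeds next to the fixtures.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]).
#' @return invisibly, the fixture manifest.
#' @export
cmdSimulate <- function(config = defaultPipelineConfig()) {
    config <- modifyList(defaultPipelineConfig(), config)
    sim <- config$simulate
    layout <- defaultLayout(nChrom = sim$n_chrom,
                            chromLength = sim$chrom_length,
                            windowSize = config$window_size,
                            seed = sim$layout_seed)
    params <- do.call(defaultParams,
                      c(config$params, list(seed = as.integer(config$seed))))
    outdir <- config$paths$output_dir
    res <- writeFixtureSet(outdir, layout, params,
                           nVarieties = sim$n_varieties,
                           writeFasta = isTRUE(sim$write_fasta))
    .writeRunSidecar(outdir, "simulate", config,
                     list(seeds = res$truth$seeds))
    message("cmdSimulate: wrote ", sim$n_varieties, " varieties to ",
            outdir)
    invisible(res)
}

#' Pipeline stage: windowed counting and correlation
#'
#' Runs parse -> threshold filter -> tile / count / intersect / label ->
#' smooth -> correlate on one dataset and writes the per-window feature
#' table, the correlation report (TSV + JSON) and its cross-chromosome
#' summary. Per-stage record counts are logged; chromosome-name mismatches
#' across the inputs raise an error listing the offenders.
#'
#' @param config a configuration list; `paths$cx_report`,
#'   `paths$recomb_map`, `paths$centromere_table` and `paths$output_dir`
#'   are required, `paths$annotations` and `paths$genome` optional.
#' @return invisibly, a list with the [WindowFeatureTable-class], the
#'   report and its summary.
#' @export
cmdCorrelate <- function(config) {
    config <- modifyList(defaultPipelineConfig(), config)
    p <- config$paths
    for (need in c("cx_report", "recomb_map", "centromere_table"))
        if (is.null(p[[need]])) stop("config paths$", need, " is required")
    records <- readCytosineReport(p$cx_report)
    message("cmdCorrelate: ", length(records), " cytosine records")
    if (!is.null(p$genome)) {
        genome <- readDNAStringSet(p$genome)
        names(genome) <- sub("\\s.*", "", names(genome))
        records <- validateContexts(records, genome)
        message("cmdCorrelate: ", attr(records, "n_mismatch"),
                " records rejected by context validation")
    }
    features <- if (!is.null(p$annotations)) readAnnotations(p$annotations)
                else GRanges(feature_class = character())
    recombMap <- readRecombinationMap(p$recomb_map)
    centromeres <- readCentromereTable(p$centromere_table)
    mapChroms <- unique(as.character(seqnames(recombMap)))
    offenders <- setdiff(unique(as.character(seqnames(records))), mapChroms)
    if (length(offenders))
        stop("chromosomes in the cytosine report missing from the ",
             "recombination map: ", paste(offenders, collapse = ", "))
    wft <- buildWindowFeatureTable(
        records, features, recombMap, centromeres,
        windowSize = config$window_size,
        levelThreshold = config$level_threshold,
        minCoverage = config$min_coverage,
        flank = config$centromere_flank)
    report <- correlationReport(wft, alpha = config$input_alpha)
    summ <- summarizeCorrelations(report)
    outdir <- p$output_dir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeWindowFeatureTable(wft, file.path(outdir, "window_table.tsv"))
    writeCorrelationReport(report,
                           file.path(outdir, "correlation_report.tsv"),
                           file.path(outdir, "correlation_report.json"))
    write_json(summ, file.path(outdir, "correlation_summary.json"),
               dataframe = "rows", auto_unbox = TRUE, digits = NA,
               na = "null")
    .writeRunSidecar(outdir, "correlate", config,
                     list(n_records = length(records)))
    message("cmdCorrelate: wrote window table and correlation report to ",
            outdir)
    invisible(list(table = wft, report = report, summary = summ))
}

#' Pipeline stage: cross-dataset prediction
#'
#' Builds the design matrices of two processed datasets (their
#' `window_table.tsv` from [cmdCorrelate()]), trains the configured
#' predictor on one, predicts the other with output smoothing, assesses per
#' chromosome, and (by default) repeats with the roles swapped -- the two
#' reciprocal experiments.
#'
#' @param configTrain,configTest configuration lists of the two datasets;
#'   window size, features and smoothing must agree.
#' @param outputDir directory for predictions and assessments; defaults to
#'   the training dataset's output directory.
#' @param reciprocal also run the swapped direction.
#' @return invisibly, a named list of directions, each with `predictions`
#'   and `assessment`.
#' @export
cmdPredict <- function(configTrain, configTest, outputDir = NULL,
                       reciprocal = TRUE) {
    configTrain <- modifyList(defaultPipelineConfig(), configTrain)
    configTest <- modifyList(defaultPipelineConfig(), configTest)
    if (!isTRUE(all.equal(configTrain$window_size, configTest$window_size)))
        stop("datasets were windowed at different sizes: ",
             configTrain$window_size, " vs ", configTest$window_size)
    if (is.null(outputDir)) outputDir <- configTrain$paths$output_dir
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    load <- function(cfg) {
        f <- file.path(cfg$paths$output_dir, "window_table.tsv")
        if (!file.exists(f))
            stop("window table not found (run cmdCorrelate first): ", f)
        buildDesign(readWindowFeatureTable(f),
                    features = unlist(cfg$features),
                    inputAlpha = cfg$input_alpha,
                    datasetId = cfg$dataset_id)
    }
    dTrain <- load(configTrain)
    dTest <- load(configTest)
    runDir <- function(dsTrain, dsTest, tag) {
        model <- fitPredictor(dsTrain, algorithm = configTrain$algorithm,
                              numTrees = configTrain$num_trees,
                              seed = configTrain$model_seed)
        pred <- crossDatasetPredict(model, dsTest,
                                    outputAlpha = configTrain$output_alpha)
        assess <- assessPredictions(pred$predicted, pred$observed,
                                    pred$chrom)
        fwrite(as.data.table(pred),
               file.path(outputDir, paste0("predictions_", tag, ".tsv")),
               sep = "\t")
        write_json(assess,
                   file.path(outputDir, paste0("assessment_", tag,
                                               ".json")),
                   dataframe = "rows", auto_unbox = TRUE, digits = NA,
                   na = "null")
        list(predictions = pred, assessment = assess)
    }
    tagAB <- paste0(configTrain$dataset_id, "_to_", configTest$dataset_id)
    out <- list()
    out[[tagAB]] <- runDir(dTrain, dTest, tagAB)
    if (reciprocal) {
        tagBA <- paste0(configTest$dataset_id, "_to_",
                        configTrain$dataset_id)
        out[[tagBA]] <- runDir(dTest, dTrain, tagBA)
    }
    .writeRunSidecar(outputDir, "predict",
                     list(train = configTrain, test = configTest))
    message("cmdPredict: wrote predictions and assessments to ", outputDir)
    invisible(out)
}
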