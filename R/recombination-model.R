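#' Build a design matrix for recombination modelling
#'
#' Pools all chromosomes of one dataset into a row-per-window design: the
#' requested methylated-cytosine count columns are the features and the
#' recombination rate is the target, each exponentially smoothed per
#' chromosome (in window order, never across a chromosome boundary) before
#' pooling.
#'
#' @param wft a [WindowFeatureTable-class].
#' @param features feature columns; default the three context counts. The
#'   documented single-feature predictor uses `"m_CHH"` only.
#' @param inputAlpha smoothing factor applied to features and target
#'   (default 0.1).
#' @param datasetId identifier kept in the provenance columns.
#' @return `data.frame` with columns `dataset`, `chrom`, `window_index`,
#'   the features, and `target`; attributes `features` and `inputAlpha`.
#' @export
buildDesign <- function(wft, features = c("m_CG", "m_CHG", "m_CHH"),
                        inputAlpha = 0.1, datasetId = "dataset") {
    df <- windowData(wft)
    missing <- setdiff(features, colnames(df))
    if (length(missing))
        stop("requested feature(s) absent from the table: ",
             paste(missing, collapse = ", "))
    if (anyNA(df$recomb_rate))
        stop("undefined recombination rate in the table")
    out <- list()
    for (ch in unique(df$chrom)) {
        d <- df[df$chrom == ch, ]
        d <- d[order(d$index), ]
        sm <- data.frame(dataset = datasetId, chrom = ch,
                         window_index = d$index, stringsAsFactors = FALSE)
        for (v in features) sm[[v]] <- expSmooth(d[[v]], inputAlpha)
        sm$target <- expSmooth(d$recomb_rate, inputAlpha)
        out[[ch]] <- sm
    }
    design <- do.call(rbind, out)
    rownames(design) <- NULL
    attr(design, "features") <- features
    attr(design, "inputAlpha") <- inputAlpha
    design
}

#' Fit the recombination predictor
#'
#' Fits a tree-ensemble regressor on all rows of a design matrix. The
#' default is extremely-randomized trees (random split points, no
#' bootstrap: every tree sees the full training set), the study's
#' best-performing algorithm; `"random_forest"` is available for
#' comparison.
#'
#' @param design a design matrix from [buildDesign()].
#' @param algorithm `"extra_trees"` or `"random_forest"`.
#' @param numTrees ensemble size (default 100).
#' @param seed integer seed fixing the ensemble (default 42).
#' @param minNodeSize minimal node size (ranger regression default, 5).
#' @return a `recombModel` list: `model` (ranger fit), `features`,
#'   `algorithm`, `inputAlpha`, `seed`. Serializable with [saveModel()].
#' @export
fitPredictor <- function(design, algorithm = c("extra_trees",
                                               "random_forest"),
                         numTrees = 100, seed = 42L, minNodeSize = 5) {
    algorithm <- match.arg(algorithm)
    if (nrow(design) < 2) stop("training design must have at least 2 rows")
    feats <- attr(design, "features")
    x <- design[, feats, drop = FALSE]
    fit <- ranger(
        x = x, y = design$target,
        num.trees = numTrees,
        mtry = length(feats),
        min.node.size = minNodeSize,
        splitrule = if (algorithm == "extra_trees") "extratrees"
                    else "variance",
        num.random.splits = 1,
        replace = FALSE,
        sample.fraction = if (algorithm == "extra_trees") 1 else 0.632,
        seed = as.integer(seed),
        num.threads = 1
    )
    structure(list(model = fit, features = feats, algorithm = algorithm,
                   inputAlpha = attr(design, "inputAlpha"),
                   seed = as.integer(seed)),
              class = "recombModel")
}

#' Predict from a fitted recombination model
#'
#' @param model a `recombModel` from [fitPredictor()].
#' @param newdata `data.frame` containing the model's feature columns.
#' @return numeric predictions (raw, unsmoothed).
#' @export
predictRecombination <- function(model, newdata) {
    stopifnot(inherits(model, "recombModel"))
    missing <- setdiff(model$features, colnames(newdata))
    if (length(missing))
        stop("feature mismatch: newdata lacks ",
             paste(missing, collapse = ", "))
    predict(model$model, data = newdata[, model$features, drop = FALSE],
            num.threads = 1)$predictions
}

#' @rdname fitPredictor
#' @param model a `recombModel`.
#' @param path file path for the serialized model.
#' @export
saveModel <- function(model, path) {
    saveRDS(model, path)
    invisible(path)
}

#' @rdname fitPredictor
#' @export
readModel <- function(path) readRDS(path)

#' Cross-dataset prediction with output smoothing
#'
#' Predicts the recombination rate for every window of a test design built
#' with the same features and input smoothing as the training design, then
#' exponentially smooths the raw predictions per chromosome (default
#' `alpha = 0.3`).
#'
#' @param model a `recombModel` from [fitPredictor()].
#' @param designTest a design matrix from [buildDesign()].
#' @param outputAlpha smoothing factor for the model output (default 0.3).
#' @return `data.frame` with `dataset`, `chrom`, `window_index`,
#'   `observed`, `predicted_raw`, `predicted` (smoothed).
#' @export
crossDatasetPredict <- function(model, designTest, outputAlpha = 0.3) {
    feats <- attr(designTest, "features")
    if (!identical(feats, model$features))
        stop("feature mismatch: model uses (",
             paste(model$features, collapse = ", "), "), test design has (",
             paste(feats, collapse = ", "), ")")
    if (!isTRUE(all.equal(attr(designTest, "inputAlpha"),
                          model$inputAlpha)))
        stop("input smoothing mismatch between training and test designs")
    raw <- predictRecombination(model, designTest)
    out <- data.frame(dataset = designTest$dataset,
                      chrom = designTest$chrom,
                      window_index = designTest$window_index,
                      observed = designTest$target,
                      predicted_raw = raw,
                      stringsAsFactors = FALSE)
    out$predicted <- NA_real_
    for (ch in unique(out$chrom)) {
        i <- which(out$chrom == ch)
        i <- i[order(out$window_index[i])]
        out$predicted[i] <- expSmooth(out$predicted_raw[i], outputAlpha)
    }
    out
}

#' Per-chromosome prediction assessment
#'
#' Computes, per chromosome, the coefficient of determination
#' `R2 = 1 - SS_res / SS_tot`, MSE, RMSE (`sqrt(MSE)`) and the Pearson
#' correlation between predictions and observations, plus the
#' cross-chromosome mean and standard deviation of each metric. A constant
#' observed series yields an undefined (`NA`) R2 and correlation.
#'
#' @param predicted,observed numeric vectors, aligned per window.
#' @param chrom chromosome of each window.
#' @return list with `perChromosome` and `summary` data frames.
#' @export
assessPredictions <- function(predicted, observed, chrom) {
    stopifnot(length(predicted) == length(observed),
              length(observed) == length(chrom))
    per <- do.call(rbind, lapply(split(seq_along(chrom), chrom),
                                 function(i) {
        if (length(i) < 3)
            stop("fewer than 3 windows on chromosome ", chrom[i][1])
        o <- observed[i]; p <- predicted[i]
        ssTot <- sum((o - mean(o))^2)
        ssRes <- sum((o - p)^2)
        mse <- mean((o - p)^2)
        data.frame(chrom = chrom[i][1],
                   n_windows = length(i),
                   r2 = if (ssTot == 0) NA_real_ else 1 - ssRes / ssTot,
                   mse = mse, rmse = sqrt(mse),
                   pearson_r = pearsonR(p, o),
                   stringsAsFactors = FALSE)
    }))
    rownames(per) <- NULL
    metrics <- c("r2", "mse", "rmse", "pearson_r")
    summ <- data.frame(
        metric = metrics,
        mean = vapply(metrics, function(m) mean(per[[m]], na.rm = TRUE),
                      numeric(1)),
        sd = vapply(metrics, function(m) sd(per[[m]], na.rm = TRUE),
                    numeric(1)),
        n_defined = vapply(metrics, function(m) sum(!is.na(per[[m]])),
                           numeric(1)),
        stringsAsFactors = FALSE)
    rownames(summ) <- NULL
    list(perChromosome = per, summary = summ)
}

.REGRESSOR_PANEL <- c("mean_baseline", "linear_regression",
                      "k_nearest_neighbors", "random_forest", "extra_trees",
                      "gradient_boosting")

.fitPanelModel <- function(name, x, y, seed) {
    set.seed(seed)
    switch(name,
        mean_baseline = {
            mu <- mean(y)
            function(newx) rep(mu, nrow(newx))
        },
        linear_regression = {
            fit <- lm(y ~ ., data = cbind(x, y = y))
            function(newx) unname(predict(fit, newdata = newx))
        },
        k_nearest_neighbors = {
            fit <- knnreg(x, y, k = 5)
            function(newx) unname(predict(fit, newdata = newx))
        },
        random_forest = {
            fit <- randomForest(x, y, ntree = 100)
            function(newx) unname(predict(fit, newdata = newx))
        },
        extra_trees = {
            fit <- ranger(x = x, y = y, num.trees = 100,
                          mtry = ncol(x), splitrule = "extratrees",
                          num.random.splits = 1, replace = FALSE,
                          sample.fraction = 1, seed = seed,
                          num.threads = 1)
            function(newx) predict(fit, data = newx,
                                   num.threads = 1)$predictions
        },
        gradient_boosting = {
            fit <- xgboost(x = as.matrix(x), y = y,
                           objective = "reg:squarederror", nrounds = 100,
                           nthreads = 1, seed = seed, verbosity = 0)
            function(newx) predict(fit, as.matrix(newx))
        },
        stop("unknown panel model: ", name)
    )
}

#' Compare a fixed panel of regressors on a shuffled holdout
#'
#' A single seeded shuffled split (default 80/20); each panel model is fit
#' on the training part and scored on the holdout by R2 and RMSE, then
#' ranked by R2 descending. The default panel: mean-predictor baseline,
#' linear regression, k-nearest-neighbours, random forest, extra trees,
#' gradient boosting.
#'
#' @param design a design matrix from [buildDesign()] (>= 20 rows).
#' @param panel character vector of panel model names.
#' @param holdoutFraction fraction held out (default 0.2).
#' @param seed integer seed for the split and the stochastic fits.
#' @return `data.frame` (`model`, `r2`, `rmse`) ranked by holdout R2;
#'   a constant holdout target yields undefined (`NA`) R2.
#' @export
compareRegressors <- function(design, panel = .REGRESSOR_PANEL,
                              holdoutFraction = 0.2, seed = 42L) {
    stopifnot(length(panel) >= 1, nrow(design) >= 20)
    feats <- attr(design, "features")
    x <- design[, feats, drop = FALSE]
    y <- design$target
    set.seed(seed)
    n <- nrow(design)
    hold <- sample(n, max(1, floor(holdoutFraction * n)))
    xtr <- x[-hold, , drop = FALSE]; ytr <- y[-hold]
    xte <- x[hold, , drop = FALSE]; yte <- y[hold]
    ssTot <- sum((yte - mean(yte))^2)
    rows <- lapply(seq_along(panel), function(i) {
        predictor <- .fitPanelModel(panel[i], xtr, ytr, seed + i)
        p <- predictor(xte)
        data.frame(model = panel[i],
                   r2 = if (ssTot == 0) NA_real_
                        else 1 - sum((yte - p)^2) / ssTot,
                   rmse = sqrt(mean((yte - p)^2)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$r2, na.last = TRUE), ]
    rownames(out) <- NULL
    out
}
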