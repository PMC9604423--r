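#' Exact Shapley feature attribution by coalition enumeration
#'
#' Computes exact Shapley values for a regression model by enumerating all
#' `2^k` feature coalitions, with the value of a coalition S defined by
#' background marginalisation: `v(S)` is the mean model prediction over the
#' background rows after substituting the explained row's values for the
#' features in S. The attribution satisfies the efficiency identity
#' `baseline + sum(contributions) = prediction` exactly (to floating point)
#' for every row, as well as the dummy and symmetry axioms. Feasible for
#' up to 12 features; this pipeline uses at most 3 (the CG, CHG and CHH
#' methylated-cytosine counts).
#'
#' @param predictFn function taking a `data.frame` with the feature columns
#'   and returning numeric predictions.
#' @param X `data.frame` of rows to explain (features only).
#' @param background non-empty `data.frame` of background rows (same
#'   columns).
#' @return list with `values` (matrix, rows of `X` by features), `baseline`
#'   (mean prediction over the background, `v(empty)`), and `meanAbs`
#'   (named per-feature mean absolute contribution).
#' @examples
#' f <- function(d) 2 * d$a + d$b
#' X <- data.frame(a = c(1, 2), b = c(0, 1))
#' shapleyValues(f, X, X)
#' @export
shapleyValues <- function(predictFn, X, background) {
    X <- as.data.frame(X)
    background <- as.data.frame(background)
    stopifnot(nrow(background) >= 1, identical(colnames(X),
                                               colnames(background)))
    k <- ncol(X)
    if (k > 12)
        stop("more than 12 features: exact coalition enumeration is ",
             "infeasible; a sampling approximation is out of scope")
    n <- nrow(X)
    m <- nrow(background)
    masks <- 0:(2^k - 1)
    inMask <- vapply(seq_len(k),
                     function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0L,
                     logical(length(masks)))
    if (is.null(dim(inMask))) inMask <- matrix(inMask, nrow = length(masks))
    # v[i, s]: mean prediction over background with coalition s taken from
    # row i of X
    v <- matrix(NA_real_, n, length(masks))
    bgIdx <- rep(seq_len(m), times = n)
    rowIdx <- rep(seq_len(n), each = m)
    for (s in seq_along(masks)) {
        z <- background[bgIdx, , drop = FALSE]
        take <- which(inMask[s, ])
        for (j in take) z[[j]] <- X[[j]][rowIdx]
        pred <- predictFn(z)
        v[, s] <- rowsum(pred, rowIdx)[, 1] / m
    }
    sizes <- rowSums(inMask)
    # weight of a coalition S not containing j: |S|! (k-|S|-1)! / k!
    w <- ifelse(sizes == k, 0,
                factorial(sizes) * factorial(pmax(0, k - sizes - 1)) /
                    factorial(k))
    values <- matrix(0, n, k, dimnames = list(NULL, colnames(X)))
    for (j in seq_len(k)) {
        without <- which(!inMask[, j])
        with <- without + 2^(j - 1)   # mask index offset for adding j
        contrib <- (v[, with, drop = FALSE] - v[, without, drop = FALSE]) %*%
            w[without]
        values[, j] <- contrib
    }
    list(values = values,
         baseline = v[1, 1],
         meanAbs = colMeans(abs(values)))
}

#' Shapley attribution report for a fitted recombination model
#'
#' Subsamples explained and background rows from a design matrix (seeded),
#' then runs [shapleyValues()] against the model's prediction function.
#'
#' @param model a fitted model from [fitPredictor()].
#' @param design a design matrix from [buildDesign()] (its feature columns
#'   must match the model's).
#' @param nExplain maximum number of rows to explain.
#' @param nBackground maximum number of background rows.
#' @param seed integer seed for the subsampling.
#' @return as [shapleyValues()], plus `rows` (indices of explained rows).
#' @export
shapleyReport <- function(model, design, nExplain = 200, nBackground = 100,
                          seed = 1L) {
    feats <- model$features
    if (!all(feats %in% colnames(design)))
        stop("design lacks the model's features: ",
             paste(setdiff(feats, colnames(design)), collapse = ", "))
    set.seed(seed)
    ei <- sort(sample(nrow(design), min(nExplain, nrow(design))))
    bi <- sort(sample(nrow(design), min(nBackground, nrow(design))))
    out <- shapleyValues(function(d) predictRecombination(model, d),
                         design[ei, feats, drop = FALSE],
                         design[bi, feats, drop = FALSE])
    out$rows <- ei
    out
}
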