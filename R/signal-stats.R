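#' Simple exponential smoothing
#'
#' `s[1] = x[1]`; `s[t] = alpha * x[t] + (1 - alpha) * s[t-1]`. Applied per
#' chromosome in window order throughout the package; the recursion never
#' crosses a chromosome boundary. The output stays within `[min(x), max(x)]`
#' and the filter is scale-equivariant.
#'
#' @param x numeric series (non-empty, no NA).
#' @param alpha smoothing factor in (0, 1]; `alpha = 1` is the identity.
#' @return smoothed series, same length as `x`.
#' @examples
#' expSmooth(c(0, 10, 10), 0.1)  # 0.0 1.0 1.9
#' expSmooth(c(0, 10, 10), 0.3)  # 0.0 3.0 5.1
#' @export
expSmooth <- function(x, alpha) {
    if (length(x) == 0L) stop("empty series")
    stopifnot(alpha > 0, alpha <= 1)
    if (anyNA(x)) stop("series contains NA")
    if (length(x) == 1L) return(x)
    as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                             init = x[1]))
}

#' Pearson correlation with an undefined marker
#'
#' Standard product-moment correlation; returns `NA` (rather than raising)
#' when either series is constant or shorter than 3, so that degenerate
#' strata propagate as undefined rows instead of aborting a report.
#'
#' @param x,y numeric series of equal length.
#' @return correlation in [-1, 1], or `NA` when undefined.
#' @export
pearsonR <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (length(x) < 3L) return(NA_real_)
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = "pearson")
}

.CORR_VARIABLES <- c("m_all", "m_CG", "m_CHG", "m_CHH", "gene_n", "te_n",
                     "retro_n", "m_in_gene", "m_in_te", "m_in_retro")
.STRATA <- c("whole", "arm", "centromere_region")

#' Smooth every per-window signal of a feature table
#'
#' Applies [expSmooth()] per chromosome, in window order, to each count
#' variable and to the recombination rate.
#'
#' @param wft a [WindowFeatureTable-class].
#' @param alpha smoothing factor.
#' @return `data.frame` as [windowData()] with every variable replaced by
#'   its smoothed version.
#' @export
smoothWindowTable <- function(wft, alpha = 0.1) {
    df <- windowData(wft)
    vars <- c(.CORR_VARIABLES, "recomb_rate")
    for (ch in unique(df$chrom)) {
        i <- which(df$chrom == ch)
        i <- i[order(df$index[i])]
        for (v in vars) df[[v]][i] <- expSmooth(df[[v]][i], alpha)
    }
    df
}

#' Per-chromosome, stratum-aware correlation report
#'
#' For every chromosome, every variable of the table and every stratum
#' (whole chromosome, arms, centromere region), reports the Pearson
#' correlation between the exponentially smoothed variable and the
#' exponentially smoothed recombination rate. Smoothing is applied to the
#' whole chromosome series first, then the stratified subset is taken (the
#' strata are not re-smoothed). Strata with fewer than 3 windows, or with a
#' constant series, are emitted with an undefined (`NA`) correlation.
#'
#' @param wft a [WindowFeatureTable-class].
#' @param alpha smoothing factor (default 0.1).
#' @param variables variables to report (default: all ten).
#' @param strata strata to report (default: whole, arm, centromere_region).
#' @return `data.frame` with columns `chrom`, `variable`, `stratum`,
#'   `pearson_r`, `n_windows`.
#' @export
correlationReport <- function(wft, alpha = 0.1,
                              variables = .CORR_VARIABLES,
                              strata = .STRATA) {
    sm <- smoothWindowTable(wft, alpha)
    rows <- list()
    for (ch in unique(sm$chrom)) {
        d <- sm[sm$chrom == ch, ]
        d <- d[order(d$index), ]
        sel <- list(
            whole = rep(TRUE, nrow(d)),
            arm = d$region_label == "arm",
            centromere_region = d$region_label == "centromere_region"
        )
        for (v in variables) for (st in strata) {
            k <- sel[[st]]
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = ch, variable = v, stratum = st,
                pearson_r = pearsonR(d[[v]][k], d$recomb_rate[k]),
                n_windows = sum(k), stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Summarise a correlation report across chromosomes
#'
#' Mean and standard deviation of the per-chromosome correlations for every
#' (variable, stratum) pair. Undefined correlations are excluded and
#' counted. Reports from several datasets can be concatenated (`rbind`)
#' before summarising to pool varieties.
#'
#' @param report output of [correlationReport()] (or several, row-bound).
#' @return `data.frame` with `variable`, `stratum`, `mean_r`, `sd_r`,
#'   `n_chromosomes`, `n_undefined`.
#' @export
summarizeCorrelations <- function(report) {
    key <- interaction(report$variable, report$stratum, drop = TRUE)
    parts <- split(report, key)
    out <- do.call(rbind, lapply(parts, function(p) {
        r <- p$pearson_r
        data.frame(variable = p$variable[1], stratum = p$stratum[1],
                   mean_r = mean(r, na.rm = TRUE),
                   sd_r = sd(r, na.rm = TRUE),
                   n_chromosomes = sum(!is.na(r)),
                   n_undefined = sum(is.na(r)),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
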