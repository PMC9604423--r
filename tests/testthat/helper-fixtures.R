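# Shared fixtures and independent oracles for the test suite.
# Everything here is generated in code; nothing is read from disk.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

# ---- independent brute-force oracles (plain double loops, no GRanges) ----

# per-window per-context methylated-cytosine counts; windows are 0-based
# half-open [start0, end0), record positions 1-based
oracleMethCounts <- function(recs, wins) {
    out <- matrix(0L, nrow(wins), 3,
                  dimnames = list(NULL, c("CG", "CHG", "CHH")))
    for (i in seq_len(nrow(recs))) {
        p0 <- recs$pos[i] - 1
        for (w in seq_len(nrow(wins))) {
            if (recs$chrom[i] == wins$chrom[w] &&
                p0 >= wins$start0[w] && p0 < wins$end0[w]) {
                out[w, recs$context[i]] <- out[w, recs$context[i]] + 1L
            }
        }
    }
    out
}

# per-window feature counts under the midpoint rule
oracleFeatureCounts <- function(feats, wins) {
    out <- integer(nrow(wins))
    for (i in seq_len(nrow(feats))) {
        mid0 <- floor((feats$start0[i] + feats$end0[i]) / 2)
        for (w in seq_len(nrow(wins))) {
            if (feats$chrom[i] == wins$chrom[w] &&
                mid0 >= wins$start0[w] && mid0 < wins$end0[w])
                out[w] <- out[w] + 1L
        }
    }
    out
}

# union membership of records in feature intervals
oracleInFeature <- function(recs, feats) {
    keep <- logical(nrow(recs))
    for (i in seq_len(nrow(recs))) {
        p0 <- recs$pos[i] - 1
        for (f in seq_len(nrow(feats))) {
            if (recs$chrom[i] == feats$chrom[f] &&
                p0 >= feats$start0[f] && p0 < feats$end0[f]) {
                keep[i] <- TRUE
                break
            }
        }
    }
    keep
}

# ---- independent Shapley enumerator (permutation average) ----

allPermutations <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (p in allPermutations(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], p)
    out
}

# Shapley values for one row by averaging marginal contributions over all
# feature orderings; same value function (background marginalisation) but a
# different algorithm than the coalition-weight sum under test
permutationShapley <- function(f, xrow, background) {
    k <- ncol(xrow)
    vfun <- function(S) {
        z <- background
        for (j in S) z[[j]] <- xrow[[j]][1]
        mean(f(z))
    }
    phi <- numeric(k)
    perms <- allPermutations(seq_len(k))
    for (p in perms) {
        S <- integer(0)
        for (j in p) {
            phi[j] <- phi[j] + vfun(c(S, j)) - vfun(S)
            S <- c(S, j)
        }
    }
    setNames(phi / length(perms), colnames(xrow))
}

# ---- toy WindowFeatureTable built directly from per-window values ----

toyWFT <- function(chromLengths, windowSize, values, centromeres = NULL,
                   flank = 2e6) {
    w <- tileWindows(chromLengths, windowSize)
    if (!is.null(centromeres)) w <- labelRegions(w, centromeres, flank)
    n <- length(w)
    defaults <- list(m_CG = 0L, m_CHG = 0L, m_CHH = 0L, gene_n = 0L,
                     te_n = 0L, retro_n = 0L, m_in_gene = 0L, m_in_te = 0L,
                     m_in_retro = 0L, recomb_rate = 0)
    d <- lapply(defaults, rep, length.out = n)
    for (nm in names(values)) d[[nm]] <- values[[nm]]
    d$m_all <- d$m_CG + d$m_CHG + d$m_CHH
    new("WindowFeatureTable", windows = w, data = do.call(DataFrame, d),
        windowSize = as.numeric(windowSize))
}

# ---- cached default paired fixture (built once per test run) ----

.fixtureEnv <- new.env(parent = emptyenv())

defaultFixturePair <- function() {
    if (is.null(.fixtureEnv$pair)) {
        layout <- defaultLayout()
        params <- defaultParams()   # params seed 1 -> variety seeds 1, 1001
        build <- function(seed) {
            sim <- simulateVariety(layout, params, seed)
            wft <- buildWindowFeatureTable(
                sim$records, sim$features, sim$recombMap, sim$centromeres,
                chromLengths = layout@chromLengths)
            list(wft = wft, truth = sim$truth)
        }
        .fixtureEnv$pair <- list(layout = layout, params = params,
                                 A = build(1L), B = build(1001L))
    }
    .fixtureEnv$pair
}
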