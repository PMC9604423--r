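.designToy <- function() {
    # two chromosomes, deterministic values
    wft <- toyWFT(c(c1 = 3e5, c2 = 3e5), 1e5,
                  values = list(m_CHH = c(0L, 10L, 10L, 4L, 8L, 2L),
                                m_CG = c(5L, 5L, 5L, 1L, 2L, 3L),
                                recomb_rate = c(0, 10, 10, 7, 7, 7)))
    wft
}

test_that("design matrices smooth per chromosome and never leak across", {
    wft <- .designToy()
    d1 <- buildDesign(wft, features = c("m_CHH", "m_CG"), inputAlpha = 1)
    raw <- windowData(wft)
    expect_equal(d1$m_CHH, as.numeric(raw$m_CHH))   # alpha = 1: identity
    expect_equal(d1$target, raw$recomb_rate)

    d <- buildDesign(wft, features = "m_CHH", inputAlpha = 0.1)
    expect_equal(d$m_CHH[d$chrom == "c1"], c(0, 1.0, 1.9))  # hand recurrence
    # chromosome boundary reset: first row of c2 equals its raw value
    expect_equal(d$m_CHH[d$chrom == "c2"][1], 4)
    expect_equal(d$target[d$chrom == "c2"], c(7, 7, 7))
    expect_equal(nrow(d), 6)

    expect_error(buildDesign(wft, features = "m_XXX"), "absent")
})

test_that("the ensemble is deterministic and handles degenerate targets", {
    set.seed(1)
    n <- 80
    wft <- toyWFT(c(c1 = 8e6), 1e5,
                  values = list(m_CHH = rpois(n, 30),
                                recomb_rate = abs(rnorm(n))))
    design <- buildDesign(wft, features = "m_CHH")
    m1 <- fitPredictor(design, seed = 42)
    m2 <- fitPredictor(design, seed = 42)
    expect_identical(predictRecombination(m1, design),
                     predictRecombination(m2, design))

    # constant target -> constant predictions at that value
    dConst <- design
    dConst$target <- 0.5
    mc <- fitPredictor(dConst)
    expect_equal(predictRecombination(mc, dConst), rep(0.5, n))

    expect_error(fitPredictor(design[1, ]), "at least 2 rows")

    # training fit is at least as good as a cross-chromosome holdout
    mFit <- fitPredictor(design)
    pTrain <- predictRecombination(mFit, design)
    r2 <- function(o, p) 1 - sum((o - p)^2) / sum((o - mean(o))^2)
    expect_gte(r2(design$target, pTrain), 0)

    # serialization round-trip
    f <- tempfile(fileext = ".rds")
    saveModel(mFit, f)
    m3 <- readModel(f)
    expect_identical(predictRecombination(m3, design), pTrain)
})

test_that("output smoothing is per chromosome with the stated recurrence", {
    wft <- .designToy()
    design <- buildDesign(wft, features = "m_CHH", inputAlpha = 1)
    model <- fitPredictor(design)
    p1 <- crossDatasetPredict(model, design, outputAlpha = 1)
    expect_equal(p1$predicted, p1$predicted_raw)   # alpha = 1: unchanged
    p3 <- crossDatasetPredict(model, design, outputAlpha = 0.3)
    for (ch in c("c1", "c2")) {
        i <- p3$chrom == ch
        expect_equal(p3$predicted[i], expSmooth(p3$predicted_raw[i], 0.3))
    }

    # feature mismatch is an error
    dOther <- buildDesign(wft, features = c("m_CHH", "m_CG"),
                          inputAlpha = 1)
    expect_error(crossDatasetPredict(model, dOther), "feature mismatch")
    dAlpha <- buildDesign(wft, features = "m_CHH", inputAlpha = 0.5)
    expect_error(crossDatasetPredict(model, dAlpha), "smoothing mismatch")
})

test_that("assessment metrics match hand computation", {
    a <- assessPredictions(c(1, 2, 3), c(1, 2, 3), rep("c1", 3))
    expect_equal(a$perChromosome$r2, 1)
    expect_equal(a$perChromosome$mse, 0)
    expect_equal(a$perChromosome$pearson_r, 1)

    obs <- c(1, 2, 3)
    a2 <- assessPredictions(rep(mean(obs), 3), obs, rep("c1", 3))
    expect_equal(a2$perChromosome$r2, 0)

    # obs = [1,2,3], pred = [1,1,3]: SS_res = 1, SS_tot = 2, MSE = 1/3
    a3 <- assessPredictions(c(1, 1, 3), obs, rep("c1", 3))
    expect_equal(a3$perChromosome$r2, 0.5)
    expect_equal(a3$perChromosome$mse, 1 / 3)
    expect_equal(a3$perChromosome$rmse, sqrt(1 / 3))

    # constant observed -> undefined R2, not an error
    a4 <- assessPredictions(c(1, 2, 3), c(2, 2, 2), rep("c1", 3))
    expect_true(is.na(a4$perChromosome$r2))

    # cross-chromosome summary
    both <- assessPredictions(c(1, 1, 3, 1, 2, 3), rep(obs, 2),
                              rep(c("c1", "c2"), each = 3))
    expect_equal(both$summary$mean[both$summary$metric == "r2"],
                 mean(c(0.5, 1)))
})

test_that("the regressor panel ranks a linear truth correctly", {
    set.seed(2)
    n <- 100
    wft <- toyWFT(c(c1 = 1e7), 1e5,
                  values = list(m_CHH = rpois(n, 50),
                                recomb_rate = 0))
    design <- buildDesign(wft, features = "m_CHH", inputAlpha = 1)
    design$target <- 3 * design$m_CHH + 2          # exact linear function

    tab <- compareRegressors(design, seed = 7)
    expect_equal(nrow(tab), 6)
    lmRow <- tab[tab$model == "linear_regression", ]
    expect_equal(lmRow$r2, 1.0, tolerance = 1e-9)
    base <- tab[tab$model == "mean_baseline", ]
    expect_lte(base$r2, 1e-9)
    # ranked by holdout R2, descending
    expect_equal(tab$r2, sort(tab$r2, decreasing = TRUE, na.last = TRUE))
    # determinism: same seed, identical table
    expect_identical(tab, compareRegressors(design, seed = 7))
})

test_that("exact Shapley values satisfy the axioms and closed forms", {
    set.seed(3)
    X <- data.frame(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    bg <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))

    # dummy: a model that ignores a feature gives it zero contribution
    fDummy <- function(d) 2 * d$a - d$b
    sh <- shapleyValues(fDummy, X, bg)
    expect_equal(unname(sh$values[, "c"]), rep(0, 8))

    # linear model: contribution_j = b_j * (x_j - mean(background_j))
    fLin <- function(d) 1.5 * d$a - 2 * d$b + 0.3 * d$c + 4
    shL <- shapleyValues(fLin, X, bg)
    expect_equal(shL$values[, "a"], 1.5 * (X$a - mean(bg$a)),
                 ignore_attr = TRUE)
    expect_equal(shL$values[, "b"], -2 * (X$b - mean(bg$b)),
                 ignore_attr = TRUE)
    expect_equal(shL$baseline, mean(fLin(bg)))

    # efficiency: baseline + sum of contributions = prediction, every row
    fNl <- function(d) d$a * d$b + sin(d$c) + d$a^2
    shN <- shapleyValues(fNl, X, bg)
    expect_equal(shN$baseline + rowSums(shN$values), fNl(X),
                 tolerance = 1e-12, ignore_attr = TRUE)

    # agreement with an independent permutation-average enumerator
    for (i in c(1, 4)) {
        want <- permutationShapley(fNl, X[i, ], bg)
        expect_equal(shN$values[i, ], want, tolerance = 1e-12)
    }

    # symmetry: exchangeable features get equal credit on symmetric input
    Xs <- data.frame(a = c(2, 2), b = c(2, 2), c = c(0, 1))
    fSym <- function(d) d$a + d$b
    shS <- shapleyValues(fSym, Xs, Xs)
    expect_equal(shS$values[, "a"], shS$values[, "b"], ignore_attr = TRUE)

    expect_error(shapleyValues(fNl, X[, rep(1, 13)],
                               bg[, rep(1, 13)]),
                 "more than 12 features")
})
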