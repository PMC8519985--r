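# Wilcoxon screening, logistic regression and backward elimination.

test_that("signed-rank p-values handle zeros, signs and the worked case", {
    expect_equal(wilcoxonSignedRank(rep(0, 8)), 1)
    expect_equal(wilcoxonSignedRank(c(1, 2, 3, 4, 5)), 2 / 32)
    d <- c(1.2, -0.5, 2.1, 0.3, -1.7, 0.9, 2.4)
    expect_equal(wilcoxonSignedRank(d), wilcoxonSignedRank(-d))
    # zeros are discarded before ranking
    expect_equal(wilcoxonSignedRank(c(0, 0, 1, 2, 3, 4, 5)),
                 wilcoxonSignedRank(c(1, 2, 3, 4, 5)))
})

test_that("exact p-values match the exhaustive sign-permutation oracle,
           including under ties", {
    set.seed(21)
    for (r in 1:30) {
        n <- sample(5:12, 1)
        d <- sample(c(-3, -2, -1, 1, 2, 3, 1.5, -1.5), n, replace = TRUE)
        expect_equal(wilcoxonSignedRank(d), exhaustiveSignedRankP(d),
                     tolerance = 1e-12)
    }
})

test_that("tie-free exact p-values agree with the classical distribution", {
    set.seed(4)
    for (r in 1:10) {
        d <- round(rnorm(10), 6)   # ties almost surely absent
        ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value)
        expect_equal(wilcoxonSignedRank(d), ref, tolerance = 1e-10)
    }
})

test_that("large-sample path applies the normal approximation with
           continuity correction", {
    set.seed(8)
    d <- rnorm(40, mean = 0.3)
    ref <- suppressWarnings(stats::wilcox.test(d, correct = TRUE,
                                               exact = FALSE)$p.value)
    expect_equal(wilcoxonSignedRank(d), ref, tolerance = 1e-9)
})

test_that("screening applies the Bonferroni rule to per-patient medians", {
    tab <- simulateVoxelCohort(nPatients = 8L, voxelsPerPatient = 120L,
                               seed = 31L)
    sc <- screenParameters(tab, m = 13L)
    expect_equal(nrow(sc), 13L)
    expect_equal(sc$pAdjusted, pmin(1, sc$p * 13))
    expect_identical(sc$pass, sc$pAdjusted < 0.05)
    # a patient missing one ROI is rejected
    bad <- tab[!(tab$patient == "P001" & tab$label == 1L), ]
    expect_error(screenParameters(bad, m = 13L), "missing one ROI")
})

test_that("a parameter with identical class distributions fails the screen
           in almost all seeded runs", {
    fails <- vapply(1:20, function(r) {
        tab <- simulateVoxelCohort(nPatients = 15L, voxelsPerPatient = 150L,
                                   contrast = setdiff(mapNames(),
                                                      c("k2", "T0")),
                                   seed = 100L + r)
        sc <- screenParameters(tab, m = 13L)
        !sc$pass[sc$parameter == "k2"]
    }, logical(1))
    expect_gte(mean(fails), 0.9)
})

test_that("logistic coefficients match a Newton-Raphson oracle on a small
           worked table", {
    tab <- data.frame(
        patient = rep(c("A", "B"), each = 4),
        label = rep(c(0L, 1L), 4),
        Ki = c(0.033, 0.042, 0.031, 0.065, 0.044, 0.031, 0.046, 0.050),
        k4 = c(0.112, 0.094, 0.135, 0.108, 0.088, 0.064, 0.125, 0.099))
    m <- logisticFit(tab, c("Ki", "k4"))
    expect_false(m@separation)
    Z <- scale(as.matrix(tab[c("Ki", "k4")]))
    oracle <- newtonLogistic(Z, tab$label)
    expect_equal(unname(m@coefficients), unname(oracle), tolerance = 1e-6)
})

test_that("null-data fits satisfy the intercept score equation and give
           calibrated Wald p-values", {
    tab <- withr::with_seed(77, data.frame(
        patient = rep(c("A", "B", "C"), each = 150),
        label = rbinom(450, 1, 0.3),
        Ki = rlnorm(450, log(0.05), 0.3),
        k4 = rlnorm(450, log(0.1), 0.3)))
    m <- logisticFit(tab, c("Ki", "k4"))
    pr <- predictProb(m, tab)
    expect_equal(mean(pr), mean(tab$label), tolerance = 1e-8)
    expect_equal(unname(m@coefficients[1]),
                 log(mean(tab$label) / (1 - mean(tab$label))),
                 tolerance = 0.05)
    expect_true(all(m@waldP[-1] > 0.001))
})

test_that("degenerate designs are rejected and separation falls back to
           ridge", {
    tab <- data.frame(patient = rep(c("A", "B"), each = 4),
                      label = rep(c(0L, 1L), 4),
                      Ki = c(1, 2, 3, 4, 5, 6, 7, 8))
    tab$dup <- tab$Ki
    expect_error(logisticFit(tab, c("Ki", "dup")), "rank-deficient")
    sep <- data.frame(patient = rep(c("A", "B"), each = 10),
                      label = rep(c(0L, 1L), each = 10),
                      Ki = c(seq(0.01, 0.03, length.out = 10),
                             seq(0.05, 0.08, length.out = 10)))
    m <- logisticFit(sep, "Ki")
    expect_true(m@separation)
    expect_true(all(is.finite(m@coefficients)))
    expect_true(all(is.na(m@waldP)))
})

test_that("backward elimination drops pure-noise features and never returns
           an empty model", {
    res <- vapply(1:20, function(r) withr::with_seed(500 + r, {
        n <- 400
        tab <- data.frame(patient = rep(c("A", "B", "C", "D"), each = n / 4),
                          label = rbinom(n, 1, 0.4))
        tab$signal <- rnorm(n, mean = tab$label)
        tab$noise <- rnorm(n)
        m <- backwardEliminate(tab, c("signal", "noise"))
        c(signalKept = "signal" %in% m@features,
          noiseDropped = !"noise" %in% m@features)
    }), logical(2))
    # the informative feature always survives; the pure-noise feature is
    # removed except at the nominal Wald type-I rate
    expect_true(all(res["signalKept", ]))
    expect_gte(mean(res["noiseDropped", ]), 0.85)

    allNoise <- withr::with_seed(9, data.frame(
        patient = rep(c("A", "B"), each = 100),
        label = rbinom(200, 1, 0.5),
        a = rnorm(200), b = rnorm(200), c = rnorm(200)))
    m <- backwardEliminate(allNoise, c("a", "b", "c"))
    expect_length(m@features, 1L)
    expect_error(backwardEliminate(allNoise, character(0)), "no candidate")
})

test_that("the final eliminated model is internally consistent: every
           retained Wald p at or below the threshold, or a single feature", {
    for (r in 1:5) {
        tab <- simulateVoxelCohort(nPatients = 6L, voxelsPerPatient = 150L,
                                   seed = 700L + r)
        m <- backwardEliminate(tab, c("Ki", "k4", "BF", "MTT", "SUVlate"))
        expect_gte(length(m@features), 1L)
        if (length(m@features) > 1L)
            expect_true(all(m@waldP[-1] <= 0.05))
    }
})
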