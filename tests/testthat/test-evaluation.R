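# ROC/AUC, confusion rates, Dice, mask detection and LOPO cross-validation.

test_that("AUC follows the Mann-Whitney formulation with half-ties", {
    expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
    expect_equal(rocAuc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
    s <- c(0.9, 0.4, 0.6, 0.4, 0.2, 0.7)
    l <- c(1, 1, 1, 0, 0, 0)
    expect_equal(rocAuc(s, l), bruteAUC(s, l))
    set.seed(14)
    for (r in 1:20) {
        s <- sample(round(runif(12), 2))   # duplicates give real ties
        l <- rbinom(12, 1, 0.5)
        if (length(unique(l)) < 2) next
        expect_equal(rocAuc(s, l), bruteAUC(s, l))
        # invariance under a strictly monotone transform
        expect_equal(rocAuc(exp(3 * s), l), rocAuc(s, l))
    }
    expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC cross-checks against an established ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(3)
    s <- rnorm(60)
    l <- rbinom(60, 1, 0.5)
    ref <- as.numeric(suppressMessages(
        pROC::auc(l, s, direction = "<", levels = c(0, 1))))
    expect_equal(rocAuc(s, l), ref, tolerance = 1e-12)
})

test_that("confusion rates compute ER, FPR and FNR", {
    expect_equal(confusionRates(c(0, 1, 0, 1), c(0, 1, 0, 1)),
                 list(ER = 0, FPR = 0, FNR = 0))
    inv <- confusionRates(c(1, 0, 1), c(0, 1, 0))
    expect_equal(inv$ER, 1)
    # TP=3, FP=1, TN=5, FN=1
    pred <- c(rep(1, 3), 1, rep(0, 5), 0)
    truth <- c(rep(1, 3), 0, rep(0, 5), 1)
    cr <- confusionRates(pred, truth)
    expect_equal(cr$ER, 0.2)
    expect_equal(cr$FPR, 1 / 6)
    expect_equal(cr$FNR, 0.25)
    expect_error(confusionRates(numeric(0), numeric(0)), "empty")
})

test_that("Dice similarity handles identity, disjoint, partial and empty", {
    a <- array(FALSE, c(4, 4, 2)); a[1:2, 1:2, 1] <- TRUE
    expect_equal(dice(a, a), 1)
    b <- array(FALSE, c(4, 4, 2)); b[3:4, 3:4, 2] <- TRUE
    expect_equal(dice(a, b), 0)
    expect_equal(dice(array(FALSE, c(2, 2, 1)), array(FALSE, c(2, 2, 1))), 1)
    big <- array(FALSE, c(10, 10, 2))
    A <- big; A[1:50] <- TRUE
    B <- big; B[21:70] <- TRUE   # |A|=|B|=50, overlap 30
    expect_equal(dice(A, B), 0.6)
    expect_error(dice(a, array(FALSE, c(3, 3, 2))), "mismatch")
})

test_that("mask detection thresholds probabilities and can isolate the
           largest component", {
    pm <- array(NA_real_, c(6, 6, 2))
    pm[2:5, 2:5, ] <- 0
    expect_equal(sum(detectDilMask(pm)), 0)
    expect_equal(sum(detectDilMask(pm, threshold = 0)), sum(!is.na(pm)))
    pm[2:3, 2:3, 1] <- 0.9                     # one supra-threshold blob
    m1 <- detectDilMask(pm, 0.5)
    m2 <- detectDilMask(pm, 0.5, largestComponent = TRUE)
    expect_identical(m1, m2)
    pm[5, 5, 2] <- 0.8                         # add a smaller second blob
    m3 <- detectDilMask(pm, 0.5, largestComponent = TRUE)
    expect_equal(sum(m3), 4)
    expect_false(m3[5, 5, 2])
    expect_error(detectDilMask(pm, 1.5), "threshold")
})

test_that("LOPO CV separares a cleanly separated cohort and counts folds", {
    tab <- data.frame(
        patient = rep(c("A", "B", "C", "D"), each = 40),
        label = rep(rep(c(0L, 1L), each = 20), 4))
    tab$Ki <- ifelse(tab$label == 1L, 2, -2) + rnorm(160, 0, 0.1)
    rep1 <- lopoCv(tab, "Ki")
    expect_equal(nrow(cvFolds(rep1)), 4L)
    s <- cvSummary(rep1)
    expect_equal(s$mean[s$metric == "AUC"], 1)
    expect_equal(s$mean[s$metric == "ER"], 0)
    expect_equal(s$mean[s$metric == "Dice"], 1)
    # a duplicated patient (new id, same data) adds one fold
    dup <- tab[tab$patient == "A", ]; dup$patient <- "E"
    rep2 <- lopoCv(rbind(tab, dup), "Ki")
    expect_equal(nrow(cvFolds(rep2)), 5L)
})

test_that("a single-class held-out patient is flagged and excluded from the
           AUC aggregate", {
    tab <- data.frame(
        patient = rep(c("A", "B", "C"), each = 30),
        label = c(rep(c(0L, 1L), 15), rep(c(0L, 1L), 15), rep(0L, 30)))
    set.seed(2)
    tab$Ki <- tab$label + rnorm(90, 0, 0.4)
    rep <- lopoCv(tab, "Ki")
    expect_true(is.na(cvFolds(rep)$AUC[cvFolds(rep)$patient == "C"]))
    s <- cvSummary(rep)
    expect_equal(s$nFolds[s$metric == "AUC"], 2L)
    expect_equal(s$nFolds[s$metric == "ER"], 3L)
})
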