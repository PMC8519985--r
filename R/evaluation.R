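# Model validation: ROC/AUC, confusion rates, leave-one-patient-out
# cross-validation and Dice similarity of detected DIL masks.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, ties counted one half. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
    if (length(scores) != length(labels)) stop("length mismatch")
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L) stop("both classes must be present")
    r <- rank(scores)
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Voxel classification error rates
#'
#' `ER = (FP + FN) / N`, `FPR = FP / (FP + TN)`, `FNR = FN / (FN + TP)`.
#'
#' @param pred 0/1 predicted labels.
#' @param truth 0/1 true labels (same length, non-empty).
#' @return Named list `ER`, `FPR`, `FNR` (NA for an empty denominator).
#' @export
confusionRates <- function(pred, truth) {
    if (!length(pred)) stop("empty input")
    if (length(pred) != length(truth)) stop("length mismatch")
    pred <- as.integer(pred); truth <- as.integer(truth)
    tp <- sum(pred == 1L & truth == 1L); fp <- sum(pred == 1L & truth == 0L)
    tn <- sum(pred == 0L & truth == 0L); fn <- sum(pred == 0L & truth == 1L)
    list(ER = (fp + fn) / length(pred),
         FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
         FNR = if (fn + tp > 0) fn / (fn + tp) else NA_real_)
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are defined as
#' perfectly similar (Dice 1).
#'
#' @param maskA,maskB logical (or 0/1) arrays on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(maskA, maskB) {
    if (!identical(dim(maskA), dim(maskB)) ||
        length(maskA) != length(maskB))
        stop("grid mismatch between masks")
    a <- as.logical(maskA); b <- as.logical(maskB)
    a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE
    denom <- sum(a) + sum(b)
    if (denom == 0) return(1)
    2 * sum(a & b) / denom
}

# 26-connected components of a logical 3D array (flood fill)
connectedComponents26 <- function(mask) {
    d <- dim(mask)
    lab <- array(0L, d)
    cur <- 0L
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off <- off[rowSums(abs(off)) > 0, ]
    idx <- which(mask)
    for (start in idx) {
        if (lab[start] != 0L) next
        cur <- cur + 1L
        queue <- start
        lab[start] <- cur
        while (length(queue)) {
            v <- queue[[1L]]; queue <- queue[-1L]
            k <- arrayInd(v, d)
            nb <- sweep(off, 2, as.integer(k), "+")
            ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
                nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
            nb <- nb[ok, , drop = FALSE]
            lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
            lin <- lin[mask[lin] & lab[lin] == 0L]
            if (length(lin)) { lab[lin] <- cur; queue <- c(queue, lin) }
        }
    }
    lab
}

#' Threshold a probability map into a detected DIL mask
#'
#' Voxels with probability at or above the threshold are detected; `NA`
#' voxels (background) never are. Optionally keeps only the largest
#' 26-connected component.
#'
#' @param probMap 3D array of probabilities in `[0, 1]` (`NA` = background).
#' @param threshold detection cut-off in `[0, 1]`, default 0.5.
#' @param largestComponent keep only the largest 26-connected component?
#' @return Logical array of the same shape.
#' @export
detectDilMask <- function(probMap, threshold = 0.5,
                          largestComponent = FALSE) {
    if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
    pv <- probMap[!is.na(probMap)]
    if (length(pv) && (min(pv) < 0 || max(pv) > 1))
        stop("probabilities must lie in [0, 1]")
    m <- !is.na(probMap) & probMap >= threshold
    if (largestComponent && any(m)) {
        lab <- connectedComponents26(m)
        sizes <- tabulate(lab[lab > 0L])
        m <- lab == which.max(sizes)
    }
    m
}

#' Leave-one-patient-out cross-validation of a voxel classifier
#'
#' For each patient, fits the logistic model with the fixed feature set on
#' every other patient's voxels, scores the held-out patient, thresholds the
#' probabilities (default 0.5) for the hard classification, and computes the
#' fold's ER/FPR/FNR, the AUC on the raw probabilities, and the Dice
#' similarity between the detected and true DIL voxel sets. A held-out
#' patient with a single class gives an undefined AUC: the fold is flagged
#' (`NA`) and excluded from the AUC aggregation. The summary reports mean,
#' SD and SE across folds.
#'
#' With `opts$reselect = TRUE` the feature set is re-selected within each
#' training fold by [backwardEliminate()] from `opts$candidates` (default:
#' the given features).
#'
#' @param table a voxel table (>= 3 patients).
#' @param features feature names of the fixed classifier.
#' @param opts list: `threshold` (0.5), `reselect` (FALSE), `candidates`.
#' @return A [CVReport-class].
#' @export
lopoCv <- function(table, features, opts = list()) {
    validateVoxelTable(table, features)
    threshold <- opts$threshold %||% 0.5
    reselect <- opts$reselect %||% FALSE
    pats <- unique(table$patient)
    if (length(pats) < 3L) stop("need at least 3 patients")

    folds <- lapply(pats, function(p) {
        train <- table[table$patient != p, ]
        test <- table[table$patient == p, ]
        model <- if (reselect)
            backwardEliminate(train, opts$candidates %||% features)
        else logisticFit(train, features)
        prob <- predictProb(model, test)
        pred <- as.integer(prob >= threshold)
        cr <- confusionRates(pred, test$label)
        auc <- if (length(unique(test$label)) < 2L) NA_real_
               else rocAuc(prob, test$label)
        dc <- {
            a <- sum(pred == 1L & test$label == 1L)
            den <- sum(pred == 1L) + sum(test$label == 1L)
            if (den == 0) 1 else 2 * a / den
        }
        data.frame(patient = p, ER = cr$ER, FPR = cr$FPR, FNR = cr$FNR,
                   AUC = auc, Dice = dc)
    })
    folds <- do.call(rbind, folds)
    metrics <- c("ER", "FPR", "FNR", "AUC", "Dice")
    summ <- do.call(rbind, lapply(metrics, function(m) {
        v <- folds[[m]]; v <- v[!is.na(v)]
        data.frame(metric = m, mean = mean(v), sd = sd(v),
                   se = sd(v) / sqrt(length(v)), nFolds = length(v))
    }))
    new("CVReport", folds = folds, summary = summ,
        model = paste(features, collapse = "+"), threshold = threshold)
}
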