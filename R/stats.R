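# Parameter screening and classifier selection: paired Wilcoxon signed-rank
# tests with Bonferroni correction, voxel-wise multivariable logistic
# regression, and backward elimination.

#' Two-sided Wilcoxon signed-rank test
#'
#' Paired signed-rank test on `x - y` (or on `x` directly when `y` is
#' `NULL`). Zero differences are discarded (the classical Wilcoxon rule) and
#' ties receive midranks. For 25 or fewer non-zero differences the p-value
#' comes from the exact permutation distribution of the positive-rank sum
#' (computed by dynamic programming over all 2^n sign assignments, valid
#' under ties); larger samples use the normal approximation with tie
#' correction and continuity correction. All differences zero gives p = 1.
#'
#' @param x numeric vector (differences, or first member of the pairs).
#' @param y optional second member of the pairs.
#' @return Two-sided p-value.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5))   # 2/32
#' @export
wilcoxonSignedRank <- function(x, y = NULL) {
    d <- if (is.null(y)) x else x - y
    d <- d[is.finite(d)]
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) return(1)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    if (n <= 25L) {
        # exact: DP over doubled midranks (integers even under ties)
        r2 <- as.integer(round(2 * r))
        total <- sum(r2)
        cnt <- numeric(total + 1L)   # cnt[s+1] = #sign assignments with 2W = s
        cnt[1L] <- 1
        for (v in r2) {
            shifted <- c(numeric(v), cnt[seq_len(total + 1L - v)])
            cnt <- cnt + shifted
        }
        cnt <- cnt / 2^n
        w2 <- as.integer(round(2 * W))
        pLow <- sum(cnt[seq_len(w2 + 1L)])
        pHigh <- sum(cnt[(w2 + 1L):(total + 1L)])
        min(1, 2 * min(pLow, pHigh))
    } else {
        e <- n * (n + 1) / 4
        ties <- table(r)
        v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
        z <- W - e
        z <- (z - sign(z) * 0.5) / sqrt(v)   # continuity correction
        min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    }
}

#' Screen parametric maps by paired Wilcoxon tests
#'
#' For each parameter, forms per-patient medians within the DIL and non-DIL
#' regions, runs the paired [wilcoxonSignedRank()] test across patients, and
#' applies Bonferroni correction with `m` comparisons (default 13, the
#' number of parametric maps). A parameter passes at adjusted P < 0.05.
#'
#' @param table a voxel table (see [buildVoxelTable()]).
#' @param m number of comparisons for Bonferroni (default 13).
#' @param features columns to screen (default: the 13 maps present).
#' @param alpha significance level on the adjusted scale, default 0.05.
#' @return `data.frame` with columns `parameter`, `p`, `pAdjusted`, `pass`.
#' @export
screenParameters <- function(table, m = 13L, features = NULL, alpha = 0.05) {
    if (is.null(features)) features <- intersect(mapNames(), names(table))
    validateVoxelTable(table, features)
    if (m < 1L) stop("m must be >= 1")
    pats <- unique(table$patient)
    res <- lapply(features, function(f) {
        med <- vapply(pats, function(p) {
            sub <- table[table$patient == p, ]
            dil <- sub[[f]][sub$label == 1L]
            non <- sub[[f]][sub$label == 0L]
            if (!length(dil) || !length(non))
                stop("patient ", p, " is missing one ROI")
            c(median(dil), median(non))
        }, numeric(2))
        p <- wilcoxonSignedRank(med[1, ], med[2, ])
        data.frame(parameter = f, p = p, pAdjusted = min(1, p * m))
    })
    out <- do.call(rbind, res)
    out$pass <- out$pAdjusted < alpha
    out
}

# ---------------------------------------------------------------------------
# logistic regression

# L2-penalized logistic coefficients by damped Newton iteration: the
# complete-separation fallback. The intercept is not penalized; lambda is a
# light per-observation ridge that keeps the slopes finite.
ridgeLogistic <- function(Z, y, lambda = 0.01, maxit = 100L, tol = 1e-10) {
    X <- cbind(1, Z)
    pen <- lambda * nrow(X) * c(0, rep(1, ncol(Z)))
    b <- numeric(ncol(X))
    for (i in seq_len(maxit)) {
        eta <- drop(X %*% b)
        p <- 1 / (1 + exp(-eta))
        g <- drop(crossprod(X, y - p)) - pen * b
        H <- crossprod(X, X * (p * (1 - p))) + diag(pen)
        step <- solve(H, g)
        b <- b + step
        if (max(abs(step)) < tol) break
    }
    b
}

#' Fitted voxel-wise logistic classifier
#'
#' @slot features retained feature (map) names
#' @slot coefficients named coefficients incl. `(Intercept)`, on the
#'   standardized (z-score) feature scale
#' @slot waldP per-coefficient two-sided Wald p-values (`NA` under the ridge
#'   fallback)
#' @slot logLik maximized log-likelihood
#' @slot separation `TRUE` when complete separation forced the L2 ridge
#'   fallback
#' @slot center,scale standardization constants used at fit time
#' @export
setClass("LogisticModel",
         representation(features = "character", coefficients = "numeric",
                        waldP = "numeric", logLik = "numeric",
                        separation = "logical", center = "numeric",
                        scale = "numeric"))

setMethod("show", "LogisticModel", function(object) {
    cat(sprintf("LogisticModel (%s)%s, logLik %.3f\n",
                paste(object@features, collapse = " + "),
                if (object@separation) " [ridge fallback]" else "",
                object@logLik))
    print(data.frame(coef = round(object@coefficients, 4),
                     waldP = signif(object@waldP, 3)))
})

#' Fit a multivariable logistic classifier
#'
#' Maximum-likelihood logistic regression of the DIL label on the given
#' features, pooling voxels across patients. Features are standardized
#' internally (z-score) and coefficients are reported on that scale. Under
#' complete separation (non-finite ML) the fit falls back to a lightly
#' L2-penalized (ridge) solution, flagged in the result with Wald p-values
#' set to `NA`.
#'
#' @param table a voxel table with `label` and the feature columns.
#' @param features character vector of feature columns.
#' @return A [LogisticModel-class].
#' @export
logisticFit <- function(table, features) {
    if (!length(features)) stop("no features given")
    validateVoxelTable(table, features)
    X <- as.matrix(table[features])
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    if (any(scl == 0)) stop("constant feature column: ",
                            paste(features[scl == 0], collapse = ", "))
    Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    if (qr(cbind(1, Z))$rank < ncol(Z) + 1L)
        stop("rank-deficient design (collinear features)")
    y <- table$label
    dat <- data.frame(y = y, Z)
    names(dat) <- c("y", features)

    sepWarn <- FALSE
    fit <- withCallingHandlers(
        glm(y ~ ., family = binomial(), data = dat),
        warning = function(w) {
            sepWarn <<- TRUE   # numerically 0/1 probabilities or no convergence
            invokeRestart("muffleWarning")
        })
    separated <- (sepWarn && max(abs(coef(fit))) > 15) || !fit$converged

    if (!separated) {
        cf <- coef(fit)
        se <- sqrt(diag(vcov(fit)))
        wp <- 2 * pnorm(-abs(cf / se))
        ll <- as.numeric(stats::logLik(fit))
    } else {
        cf <- ridgeLogistic(Z, y)
        names(cf) <- c("(Intercept)", features)
        eta <- cf[1L] + drop(Z %*% cf[-1L])
        pr <- 1 / (1 + exp(-eta))
        ll <- sum(y * log(pr) + (1 - y) * log(1 - pr))
        wp <- setNames(rep(NA_real_, length(cf)), names(cf))
    }
    new("LogisticModel", features = features, coefficients = cf,
        waldP = wp, logLik = ll, separation = separated,
        center = ctr, scale = scl)
}

#' Predicted DIL probabilities from a logistic model
#'
#' @param model a [LogisticModel-class].
#' @param table a voxel table containing the model's feature columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predictProb <- function(model, table) {
    stopifnot(is(model, "LogisticModel"))
    X <- as.matrix(table[model@features])
    Z <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
    eta <- model@coefficients[1L] + drop(Z %*% model@coefficients[-1L])
    1 / (1 + exp(-eta))
}

#' Backward elimination of logistic features
#'
#' Starting from the candidate set (normally the Wilcoxon screen survivors),
#' repeatedly refits the logistic model and removes the feature with the
#' largest Wald p-value while any exceeds `alpha` (0.05), stopping when all
#' retained features are significant or a single feature remains. The final
#' model therefore has all Wald p <= alpha or size 1; elimination never
#' returns an empty model.
#'
#' @param table a voxel table.
#' @param candidates candidate feature names (non-empty).
#' @param alpha removal threshold on the Wald p-value, default 0.05.
#' @return The final [LogisticModel-class].
#' @export
backwardEliminate <- function(table, candidates, alpha = 0.05) {
    if (!length(candidates)) stop("no candidate features")
    feats <- candidates
    repeat {
        model <- logisticFit(table, feats)
        if (length(feats) == 1L) return(model)
        wp <- model@waldP[-1L]   # drop the intercept
        if (all(is.na(wp))) return(model)   # ridge fallback: no Wald basis
        worst <- which.max(wp)
        if (wp[worst] <= alpha) return(model)
        feats <- feats[-worst]
    }
}
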