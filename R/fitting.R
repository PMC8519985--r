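# Bounded multi-start weighted nonlinear least-squares estimators for the
# F2TC and ATH models.
#
# Both fitters minimize sum( w_f * (model_f - data_f)^2 ) over the frames,
# with weights proportional to frame duration: under the generator's noise
# model (variance ~ value / duration) long frames carry proportionally more
# information, and duration weighting is the standard uniform-variance-rate
# proxy. Optimization is Levenberg-Marquardt (minpack.lm) inside box bounds,
# restarted from a fixed physiological midpoint plus seeded Latin-hypercube
# points; the best weighted RSS wins.

# evaluate expr with a temporary RNG state so callers' streams are untouched
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# starts: fixed midpoint + (n-1) seeded LHS points inside [lower, upper]
makeStarts <- function(mid, lower, upper, n, seed) {
    starts <- list(mid)
    if (n > 1L) {
        u <- withSeed(seed, lhs::randomLHS(n - 1L, length(mid)))
        for (i in seq_len(n - 1L))
            starts[[i + 1L]] <- lower + u[i, ] * (upper - lower)
    }
    starts
}

runNLS <- function(residFun, starts, lower, upper) {
    best <- NULL
    for (st in starts) {
        fit <- tryCatch(
            minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                               fn = residFun,
                               control = minpack.lm::nls.lm.control(
                                   maxiter = 200, ptol = 1e-12, ftol = 1e-12)),
            error = function(e) NULL)
        if (is.null(fit)) next
        rss <- sum(fit$fvec^2)
        if (is.null(best) || rss < best$rss)
            best <- list(fit = fit, rss = rss,
                         converged = fit$info %in% 1:4)
    }
    best
}

#' Fit the F2TC model to a tissue time-activity curve
#'
#' Weighted (frame-duration) bounded Levenberg-Marquardt with multi-start.
#' `K1` is parameterized internally as `F * extraction` with extraction in
#' `[0, 1]`, so every returned fit satisfies `K1 <= F`.
#'
#' Bounds: `F, K1` in `[0, 3]` mL/min/g; `k2, k3, k4` in `[0, 3]` 1/min;
#' `W` in `[0, 30]` s; `t0` in `[0, 60]` s.
#'
#' @param tac tissue [TimeActivityCurve-class] of frame means.
#' @param aif arterial input ([AIFModel-class] or sampled curve).
#' @param schedule the acquisition [FrameSchedule-class] (>= 10 frames).
#' @param opts list: `nStarts` (default 5), `seed` (default 1), `dt`
#'   (internal grid, default 0.5 s).
#' @return A [KineticFit-class]; `isConverged()` is `FALSE` when every
#'   restart failed, and an all-zero TAC yields a flagged zero-parameter fit.
#' @examples
#' sch <- petFrameSchedule()
#' tac <- f2tcForward(dilReferenceF2TC(), petDefaultAIF(), sch)
#' fit <- fitF2TC(tac, petDefaultAIF(), sch)
#' fitParams(fit)
#' @export
fitF2TC <- function(tac, aif, schedule, opts = list()) {
    stopifnot(is(tac, "TimeActivityCurve"), is(schedule, "FrameSchedule"))
    if (nFrames(schedule) < 10L) stop("need at least 10 frames")
    y <- curveValues(tac)
    if (length(y) != nFrames(schedule))
        stop("TAC length does not match the schedule")
    if (any(y < 0)) stop("tissue TAC must be non-negative")
    nStarts <- opts$nStarts %||% 5L
    seed <- opts$seed %||% 1L
    dt <- opts$dt %||% 0.5

    if (all(y == 0)) {
        p0 <- F2TCParams(0, 0, 0, 0, 0, 0, 0)
        return(new("KineticFit", params = p0, modality = "pet",
                   fitted = y * 0, residuals = y * 0, rss = 0,
                   converged = FALSE, degenerate = TRUE,
                   nStarts = 0L))
    }

    fa <- fineAIF(aif, max(frameEnd(schedule)), dt)
    fs <- frameStart(schedule); fe <- frameEnd(schedule)
    w <- sqrt(frameDuration(schedule) / mean(frameDuration(schedule)))
    model <- function(th)   # th = (F, W, extr, k2, k3, k4, t0)
        .f2tc_frame_conv(c(th[1], th[2], th[1] * th[3], th[4], th[5], th[6],
                           th[7]), fa$A, fa$dt, fs, fe)
    residFun <- function(th) w * (model(th) - y)

    lower <- c(0, 0, 0, 0, 0, 0, 0)
    upper <- c(3, 30, 1, 3, 3, 3, 60)
    mid <- c(0.5, 10, 0.4, 0.2, 0.05, 0.1, 5)
    best <- runNLS(residFun, makeStarts(mid, lower, upper, nStarts, seed),
                   lower, upper)

    if (is.null(best)) {
        p0 <- F2TCParams(0, 0, 0, 0, 0, 0, 0)
        return(new("KineticFit", params = p0, modality = "pet",
                   fitted = y * 0, residuals = -y, rss = sum((w * y)^2),
                   converged = FALSE, degenerate = FALSE,
                   nStarts = as.integer(nStarts)))
    }
    th <- best$fit$par
    p <- F2TCParams(F = th[1], W = th[2], K1 = th[1] * th[3], k2 = th[4],
                    k3 = th[5], k4 = th[6], t0 = th[7])
    fitted <- model(th)
    new("KineticFit", params = p, modality = "pet", fitted = fitted,
        residuals = fitted - y, rss = best$rss, converged = best$converged,
        degenerate = FALSE, nStarts = as.integer(nStarts))
}

#' Fit the ATH model to a CT-perfusion enhancement curve
#'
#' Weighted bounded Levenberg-Marquardt with multi-start. Bounds:
#' `BF` in `[0, 300]` mL/min/100g, `Tc` in `[0, 30]` s, `E` in `[0, 0.95]`,
#' `Ve` in `[1, 60]` mL/100g, `T0` in `[0, 20]` s. Derived BV/MTT/PS follow
#' the central-volume and Crone-Renkin identities from the fitted vector.
#'
#' @param curve tissue enhancement [TimeActivityCurve-class] of frame means.
#' @param aif contrast arterial input.
#' @param schedule the CTP [FrameSchedule-class].
#' @param opts list: `nStarts`, `seed` as in [fitF2TC()]; `dt` internal
#'   grid (default 0.1 s).
#' @return A [KineticFit-class] holding an [ATHParams-class].
#' @export
fitATH <- function(curve, aif, schedule, opts = list()) {
    stopifnot(is(curve, "TimeActivityCurve"), is(schedule, "FrameSchedule"))
    y <- curveValues(curve)
    if (length(y) != nFrames(schedule))
        stop("curve length does not match the schedule")
    nStarts <- opts$nStarts %||% 5L
    seed <- opts$seed %||% 1L
    dt <- opts$dt %||% 0.1

    if (all(y == 0)) {
        p0 <- ATHParams(0, 0, 0, 15, 0)
        return(new("KineticFit", params = p0, modality = "ctp",
                   fitted = y * 0, residuals = y * 0, rss = 0,
                   converged = FALSE, degenerate = TRUE, nStarts = 0L))
    }

    fa <- fineAIF(aif, max(frameEnd(schedule)), dt)
    fs <- frameStart(schedule); fe <- frameEnd(schedule)
    w <- sqrt(frameDuration(schedule) / mean(frameDuration(schedule)))
    model <- function(th) .ath_frame_conv(th, fa$A, fa$dt, fs, fe)
    residFun <- function(th) w * (model(th) - y)

    lower <- c(0, 0, 0, 1, 0)
    upper <- c(300, 30, 0.95, 60, 20)
    mid <- c(50, 8, 0.3, 15, 4)
    best <- runNLS(residFun, makeStarts(mid, lower, upper, nStarts, seed),
                   lower, upper)

    if (is.null(best)) {
        p0 <- ATHParams(0, 0, 0, 15, 0)
        return(new("KineticFit", params = p0, modality = "ctp",
                   fitted = y * 0, residuals = -y, rss = sum((w * y)^2),
                   converged = FALSE, degenerate = FALSE,
                   nStarts = as.integer(nStarts)))
    }
    th <- best$fit$par
    p <- ATHParams(BF = th[1], Tc = th[2], E = th[3], Ve = th[4], T0 = th[5])
    fitted <- model(th)
    new("KineticFit", params = p, modality = "ctp", fitted = fitted,
        residuals = fitted - y, rss = best$rss, converged = best$converged,
        degenerate = FALSE, nStarts = as.integer(nStarts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
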