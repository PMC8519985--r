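# Flow-modified two-tissue-compartment (F2TC) model: impulse response,
# frame-averaged forward model, derived parameters and SUV operations.
#
# The impulse response is a rectangular vascular window of height F (the
# tissue flow) and width W, followed by the bi-exponential response of a
# reversible two-tissue compartment system:
#   H(t) = 0                                   t <  t0
#   H(t) = F                                   t0 <= t < t0 + W
#   H(t) = K1 [ (k3+k4-a) e^{-a t'} + (b-k3-k4) e^{-b t'} ] / (b - a)
# with t' = t - t0 - W (in minutes) and a,b the eigenvalues
#   a,b = [ (k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4) ] / 2 .
# H is continuous from the exchange side: H(t0+W) = K1 <= F.

#' F2TC impulse residue response
#'
#' Evaluates the analytic impulse response `H(t)` (mL/min/g) of the
#' flow-modified two-tissue-compartment model. The repeated-eigenvalue case is
#' handled by its analytic limit.
#'
#' @param p an [F2TCParams-class].
#' @param t times in seconds (vectorized).
#' @return Numeric vector, `0 <= H <= F` everywhere.
#' @examples
#' p <- dilReferenceF2TC()
#' f2tcIRF(p, c(0, 5, 60, 600))
#' @export
f2tcIRF <- function(p, t) {
    stopifnot(is(p, "F2TCParams"))
    validObject(p)
    t <- as.numeric(t)
    h <- numeric(length(t))
    h[t >= p@t0 & t < p@t0 + p@W] <- p@F
    post <- t >= p@t0 + p@W
    if (any(post)) {
        tm <- (t[post] - p@t0 - p@W) / 60   # minutes past the window
        s <- p@k2 + p@k3 + p@k4
        disc <- s^2 - 4 * p@k2 * p@k4
        if (disc > 1e-12) {
            r <- sqrt(disc)
            a <- (s - r) / 2; b <- (s + r) / 2
            h[post] <- p@K1 * ((p@k3 + p@k4 - a) * exp(-a * tm) +
                               (b - p@k3 - p@k4) * exp(-b * tm)) / r
        } else {
            a <- s / 2   # analytic limit of the repeated root
            h[post] <- p@K1 * exp(-a * tm) * (1 + (p@k3 + p@k4 - a) * tm)
        }
    }
    h
}

# ---------------------------------------------------------------------------
# fine-grid plumbing shared by the forward models and the fitters

# Resolve an AIF argument (AIFModel or sampled TimeActivityCurve) onto the
# uniform fine grid 0, dt, ..., >= tEnd. Sampled curves are linearly
# interpolated and must cover [0, tEnd].
fineAIF <- function(aif, tEnd, dt = 0.5) {
    tg <- seq(0, tEnd + dt, by = dt)
    if (is(aif, "AIFModel")) {
        A <- evalAIF(aif, tg)
    } else if (is(aif, "TimeActivityCurve")) {
        tt <- curveTime(aif)
        if (max(tt) < tEnd - 1e-9)
            stop("schedule extends past AIF support (AIF ends at ",
                 max(tt), " s, need ", tEnd, " s)")
        A <- approx(tt, curveValues(aif), xout = tg, rule = 2)$y
        A[tg < tt[1L]] <- 0
    } else stop("aif must be an AIFModel or a TimeActivityCurve")
    list(A = A, dt = dt)
}

#' F2TC forward model on a frame schedule
#'
#' Convolves the arterial input curve with the F2TC impulse response on a fine
#' internal grid (default 0.5 s, linear AIF interpolation) and averages over
#' each acquisition frame — the frame-mean activity concentration a PET scan
#' reports. Linear in the AIF.
#'
#' @param p an [F2TCParams-class].
#' @param aif an [AIFModel-class] or a sampled [TimeActivityCurve-class]
#'   covering the schedule span.
#' @param schedule a [FrameSchedule-class].
#' @param dt internal convolution grid step, seconds.
#' @return A [TimeActivityCurve-class] of frame means at frame midpoints.
#' @export
f2tcForward <- function(p, aif, schedule, dt = 0.5) {
    stopifnot(is(p, "F2TCParams"), is(schedule, "FrameSchedule"))
    validObject(p)
    fa <- fineAIF(aif, max(frameEnd(schedule)), dt)
    v <- .f2tc_frame_conv(c(p@F, p@W, p@K1, p@k2, p@k3, p@k4, p@t0),
                          fa$A, fa$dt, frameStart(schedule),
                          frameEnd(schedule))
    TimeActivityCurve(frameMid(schedule), v, "kBq/mL")
}

# ---------------------------------------------------------------------------
# derived parameters

#' Net uptake rate constant Ki
#'
#' `Ki = K1 * k3 / (k2 + k3)` (mL/min/g), the asymptotic Patlak slope of the
#' irreversible (`k4 = 0`) system.
#'
#' @param p an [F2TCParams-class].
#' @return Ki in mL/min/g.
#' @examples
#' kiOf(dilReferenceF2TC())   # 0.055
#' @export
kiOf <- function(p) {
    stopifnot(is(p, "F2TCParams"))
    if (p@k2 + p@k3 <= 0) {
        if (p@K1 == 0) return(0)
        stop("Ki undefined: k2 = k3 = 0")
    }
    p@K1 * p@k3 / (p@k2 + p@k3)
}

#' Distribution volume DV
#'
#' `DV = (K1/k2) * (1 + k3/k4)` (mL/g), the equilibrium tissue-to-plasma
#' ratio of the exchangeable compartments (the vascular window is excluded).
#' Undefined when `k2` or `k4` is zero: returns `NA` with a warning rather
#' than a silent number.
#'
#' @param p an [F2TCParams-class].
#' @return DV in mL/g, or `NA` (with a warning) when undefined.
#' @examples
#' dvOf(dilReferenceF2TC())   # 2.29
#' @export
dvOf <- function(p) {
    stopifnot(is(p, "F2TCParams"))
    if (p@k2 <= 0 || p@k4 <= 0) {
        warning("DV undefined (k2 or k4 is zero); returning NA")
        return(NA_real_)
    }
    (p@K1 / p@k2) * (1 + p@k3 / p@k4)
}

# ---------------------------------------------------------------------------
# SUV operations

#' Standardized uptake value
#'
#' `SUV = concentration / (injected activity / body weight)`; with activity
#' concentration in kBq/mL, dose in MBq and weight in kg this is
#' `conc * weight / dose` in g/mL (tissue density 1 g/mL).
#'
#' @param conc activity concentration, kBq/mL (vectorized).
#' @param dose injected activity, MBq (> 0).
#' @param weight body weight, kg (> 0).
#' @return SUV in g/mL.
#' @export
suv <- function(conc, dose, weight) {
    if (!is.finite(dose) || dose <= 0) stop("injected dose must be positive")
    if (!is.finite(weight) || weight <= 0) stop("body weight must be positive")
    conc * weight / dose
}

#' Early SUV from the dynamic scan
#'
#' Mean of the frames acquired from 10 min post-injection onward (the last
#' four frames of the 22-min schedule), converted to SUV.
#'
#' @param tac tissue [TimeActivityCurve-class] of frame means (kBq/mL).
#' @param schedule the matching [FrameSchedule-class].
#' @param dose injected activity, MBq.
#' @param weight body weight, kg.
#' @return SUV_Early in g/mL.
#' @export
suvEarly <- function(tac, schedule, dose, weight) {
    stopifnot(is(tac, "TimeActivityCurve"), is(schedule, "FrameSchedule"))
    n <- nFrames(schedule)
    if (n < 4L) stop("need at least 4 frames for SUV_Early")
    if (length(curveValues(tac)) != n)
        stop("TAC length does not match the schedule")
    idx <- which(frameStart(schedule) >= 600)
    if (length(idx) == 0L) idx <- seq(n - 3L, n)
    suv(mean(curveValues(tac)[idx]), dose, weight)
}
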