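# Adiabatic tissue-homogeneity (Johnson-Wilson) model for CT perfusion:
# impulse residue function, frame-averaged forward model and the derived
# perfusion parameters BV, MTT, PS.

#' ATH impulse residue function
#'
#' `R(t) = 0` before the contrast delay `T0`; unity during the capillary
#' transit `[T0, T0 + Tc)`; `E * exp(-E*BF*(t - T0 - Tc)/(60*Ve))` afterwards
#' (the extracted fraction washing out of the interstitium).
#'
#' @param p an [ATHParams-class].
#' @param t times in seconds (vectorized).
#' @return Residue fraction in `[0, 1]`.
#' @export
athIRF <- function(p, t) {
    stopifnot(is(p, "ATHParams"))
    validObject(p)
    t <- as.numeric(t)
    r <- numeric(length(t))
    r[t >= p@T0 & t < p@T0 + p@Tc] <- 1
    post <- t >= p@T0 + p@Tc
    if (any(post) && p@E > 0) {
        kb <- p@E * p@BF / (60 * p@Ve)   # 1/s
        r[post] <- p@E * exp(-kb * (t[post] - p@T0 - p@Tc))
    }
    r
}

#' ATH forward model on a frame schedule
#'
#' Tissue enhancement `(BF/100) * (AIF (*) R)` frame-averaged on the internal
#' fine grid: indicator dilution with the per-100 g flow converted to
#' per-gram, so a unit-density voxel's enhancement shares the AIF's units.
#'
#' @param p an [ATHParams-class].
#' @param aif an [AIFModel-class] or sampled [TimeActivityCurve-class].
#' @param schedule a [FrameSchedule-class] (normally [ctpFrameSchedule()]).
#' @param dt internal grid step, seconds (default 0.1, well below the
#'   2.8 s phase-1 sampling).
#' @return A [TimeActivityCurve-class] of frame means.
#' @export
athForward <- function(p, aif, schedule, dt = 0.1) {
    stopifnot(is(p, "ATHParams"), is(schedule, "FrameSchedule"))
    validObject(p)
    fa <- fineAIF(aif, max(frameEnd(schedule)), dt)
    v <- .ath_frame_conv(c(p@BF, p@Tc, p@E, p@Ve, p@T0), fa$A, fa$dt,
                         frameStart(schedule), frameEnd(schedule))
    TimeActivityCurve(frameMid(schedule), v, "HU")
}

#' Permeability-surface-area product
#'
#' Crone-Renkin relation `PS = -BF * log(1 - E)` (mL/min/100g).
#'
#' @param BF blood flow, mL/min/100g.
#' @param E extraction fraction, `0 <= E < 1`.
#' @return PS in mL/min/100g.
#' @examples
#' psOf(56.58, 1 - exp(-24.39 / 56.58))   # 24.39
#' @export
psOf <- function(BF, E) {
    if (any(E < 0) || any(E >= 1)) stop("E must lie in [0, 1)")
    -BF * log(1 - E)
}

#' Blood volume from the central-volume principle
#'
#' `BV = BF * MTT / 60` (mL/100g) with MTT in seconds.
#'
#' @param BF blood flow, mL/min/100g.
#' @param MTT mean (capillary) transit time, seconds.
#' @return BV in mL/100g.
#' @export
bvOf <- function(BF, MTT) BF * MTT / 60
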