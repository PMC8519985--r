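# Parametric arterial input functions.
#
# The PET bolus follows the classic tri-exponential form
#   Cp(t') = (A1 t' - A2 - A3) e^{-l1 t'} + A2 e^{-l2 t'} + A3 e^{-l3 t'}
# (t' in minutes past arrival), continuous at arrival and non-negative for
# the default rate ordering l1 >> l2 > l3. The CTP bolus is a gamma variate
# with a delayed, scaled, broader recirculation gamma variate.

#' Construct a parametric AIF model
#'
#' @param model `"pet_triexp"` or `"ctp_gamma"`.
#' @param params named numeric vector; for `"pet_triexp"`: `A1` (kBq/mL/min),
#'   `A2`, `A3` (kBq/mL), `l1`, `l2`, `l3` (1/min); for `"ctp_gamma"`:
#'   `peak` (HU), `tp` (s, time-to-peak past arrival), `shape`
#'   (dimensionless), `recircFrac`, `recircDelay` (s), `recircTp` (s).
#' @param delay bolus arrival delay in seconds.
#' @return An [AIFModel-class].
#' @export
AIFModel <- function(model, params, delay = 0)
    new("AIFModel", model = model, params = params, delay = delay)

#' Default PET arterial input model
#'
#' Tri-exponential bolus peaking about 60 s post-injection, emulating an
#' image-derived iliac-artery curve after a venous bolus.
#'
#' @return An [AIFModel-class].
#' @export
petDefaultAIF <- function()
    AIFModel("pet_triexp",
             c(A1 = 40, A2 = 1.5, A3 = 1.0, l1 = 1.2, l2 = 0.3, l3 = 0.01),
             delay = 10)

#' Default CT-perfusion arterial input model
#'
#' Gamma-variate first pass (peak about 300 HU, 18 s after injection) plus a
#' 25%-amplitude recirculation bump.
#'
#' @return An [AIFModel-class].
#' @export
ctpDefaultAIF <- function()
    AIFModel("ctp_gamma",
             c(peak = 300, tp = 12, shape = 3, recircFrac = 0.25,
               recircDelay = 22, recircTp = 28),
             delay = 6)

gammaVariate <- function(tp_, peak, tp, shape) {
    y <- numeric(length(tp_))
    pos <- tp_ > 0
    r <- tp_[pos] / tp
    y[pos] <- peak * r^shape * exp(shape * (1 - r))
    y
}

#' Evaluate an AIF model at given times
#'
#' @param aif an [AIFModel-class].
#' @param times sample times in seconds, sorted, non-negative.
#' @return A [TimeActivityCurve-class]; identically zero before the model's
#'   arrival delay.
#' @examples
#' makeAIF(petDefaultAIF(), seq(0, 1330, by = 5))
#' @export
makeAIF <- function(aif, times) {
    stopifnot(is(aif, "AIFModel"))
    validObject(aif)
    times <- as.numeric(times)
    if (length(times) && (is.unsorted(times, strictly = TRUE) || times[1L] < 0))
        stop("times must be sorted, strictly increasing and non-negative")
    p <- aif@params
    tp_ <- times - aif@delay
    if (aif@model == "pet_triexp") {
        tm <- pmax(tp_, 0) / 60   # minutes past arrival
        v <- (p[["A1"]] * tm - p[["A2"]] - p[["A3"]]) * exp(-p[["l1"]] * tm) +
            p[["A2"]] * exp(-p[["l2"]] * tm) + p[["A3"]] * exp(-p[["l3"]] * tm)
        v[tp_ <= 0] <- 0
        units <- "kBq/mL"
    } else {
        v <- gammaVariate(tp_, p[["peak"]], p[["tp"]], p[["shape"]]) +
            gammaVariate(tp_ - p[["recircDelay"]],
                         p[["peak"]] * p[["recircFrac"]],
                         p[["recircTp"]], 2)
        units <- "HU"
    }
    TimeActivityCurve(times, pmax(v, 0), units)
}

# closed-form evaluation at arbitrary scalar/vector times (internal; used by
# the generator to avoid resampling errors)
evalAIF <- function(aif, times) curveValues(makeAIF(aif, times))
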