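#' @import methods
#' @importFrom stats approx median quantile rnorm rlnorm runif sd setNames
#'   glm binomial coef pnorm qnorm integrate optim vcov complete.cases
#' @importFrom utils head tail write.csv read.csv packageVersion
#' @useDynLib DILmapper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# FrameSchedule

#' Acquisition frame schedule of a dynamic scan
#'
#' Ordered, non-overlapping acquisition intervals (seconds from injection) of
#' a dynamic PET or CT-perfusion scan. Frames may be contiguous or gapped but
#' never overlap.
#'
#' @slot frameStart numeric, frame start times in seconds (strictly increasing)
#' @slot frameEnd numeric, frame end times in seconds (`frameEnd > frameStart`)
#' @export
setClass("FrameSchedule",
         representation(frameStart = "numeric", frameEnd = "numeric"))

setValidity("FrameSchedule", function(object) {
    s <- object@frameStart; e <- object@frameEnd
    if (length(s) != length(e)) return("frameStart/frameEnd length mismatch")
    if (length(s) == 0L) return("empty schedule")
    if (any(!is.finite(s)) || any(!is.finite(e))) return("non-finite frame times")
    if (any(e <= s)) return("frameEnd must exceed frameStart")
    if (length(s) > 1L) {
        if (any(diff(s) <= 0)) return("frame starts must be strictly increasing")
        if (any(s[-1L] < e[-length(e)] - 1e-9)) return("frames overlap")
    }
    TRUE
})

#' Construct a frame schedule
#'
#' @param frameStart,frameEnd frame boundaries in seconds.
#' @return A [FrameSchedule-class] object.
#' @examples
#' FrameSchedule(c(0, 10), c(10, 20))
#' @export
FrameSchedule <- function(frameStart, frameEnd)
    new("FrameSchedule", frameStart = as.numeric(frameStart),
        frameEnd = as.numeric(frameEnd))

# ---------------------------------------------------------------------------
# TimeActivityCurve

#' Time-activity (or time-enhancement) curve
#'
#' A concentration-versus-time series sampled at discrete times, e.g. a tissue
#' TAC on a frame schedule (times are frame midpoints) or an arterial input
#' curve on a fine grid.
#'
#' @slot time numeric, sample times in seconds, sorted, non-negative
#' @slot activity numeric, concentration values (units in `units`)
#' @slot units character, e.g. `"kBq/mL"` or `"HU"`
#' @export
setClass("TimeActivityCurve",
         representation(time = "numeric", activity = "numeric",
                        units = "character"))

setValidity("TimeActivityCurve", function(object) {
    if (length(object@time) != length(object@activity))
        return("time/activity length mismatch")
    if (length(object@time) && any(diff(object@time) <= 0))
        return("times must be strictly increasing")
    if (length(object@time) && object@time[1L] < 0)
        return("times must be non-negative")
    if (any(!is.finite(object@activity))) return("non-finite activity")
    TRUE
})

#' Construct a time-activity curve
#' @param time sample times (s), strictly increasing, non-negative.
#' @param activity concentration values.
#' @param units unit label carried along (not interpreted).
#' @return A [TimeActivityCurve-class] object.
#' @export
TimeActivityCurve <- function(time, activity, units = "a.u.")
    new("TimeActivityCurve", time = as.numeric(time),
        activity = as.numeric(activity), units = units)

# ---------------------------------------------------------------------------
# AIFModel

#' Parametric arterial input function
#'
#' Closed-form arterial input model: either the tri-exponential PET bolus
#' (a linear-rise-times-exponential term plus two washout exponentials,
#' continuous at bolus arrival) or a gamma-variate contrast bolus with a
#' delayed, scaled recirculation term for CT perfusion. The curve is zero
#' before the bolus-arrival delay `delay` and non-negative everywhere.
#'
#' @slot model `"pet_triexp"` or `"ctp_gamma"`
#' @slot params named numeric vector of amplitude/rate/shape terms
#' @slot delay bolus arrival delay in seconds
#' @export
setClass("AIFModel",
         representation(model = "character", params = "numeric",
                        delay = "numeric"))

setValidity("AIFModel", function(object) {
    if (!object@model %in% c("pet_triexp", "ctp_gamma"))
        return("model must be 'pet_triexp' or 'ctp_gamma'")
    need <- if (object@model == "pet_triexp")
        c("A1", "A2", "A3", "l1", "l2", "l3")
    else c("peak", "tp", "shape", "recircFrac", "recircDelay", "recircTp")
    if (!all(need %in% names(object@params)))
        return(paste("missing AIF parameters:",
                     paste(setdiff(need, names(object@params)), collapse = ", ")))
    rates <- if (object@model == "pet_triexp")
        object@params[c("l1", "l2", "l3")]
    else object@params[c("tp", "shape", "recircTp")]
    if (any(rates < 0)) return("negative rate/shape terms")
    if (object@delay < 0) return("negative bolus delay")
    TRUE
})

# ---------------------------------------------------------------------------
# Kinetic parameter vectors

#' Flow-modified two-tissue-compartment (F2TC) parameters
#'
#' The model prepends a rectangular vascular transit window (flow `F`, width
#' `W`) to a reversible two-tissue compartment system (rates `K1, k2, k3, k4`)
#' with a tissue bolus delay `t0`. Extraction is at most unity, so `K1 <= F`.
#'
#' @slot F blood flow, mL/min/g
#' @slot W vascular transit window width, seconds
#' @slot K1 influx rate constant, mL/min/g
#' @slot k2 efflux rate constant, 1/min
#' @slot k3 binding rate constant, 1/min
#' @slot k4 dissociation rate constant, 1/min
#' @slot t0 tissue bolus delay, seconds
#' @export
setClass("F2TCParams",
         representation(F = "numeric", W = "numeric", K1 = "numeric",
                        k2 = "numeric", k3 = "numeric", k4 = "numeric",
                        t0 = "numeric"))

setValidity("F2TCParams", function(object) {
    v <- c(object@F, object@W, object@K1, object@k2, object@k3, object@k4,
           object@t0)
    if (length(v) != 7L || any(!is.finite(v))) return("all slots scalar finite")
    if (any(v < 0)) return("all parameters must be non-negative")
    if (object@K1 > object@F + 1e-9) return("K1 must not exceed F (extraction <= 1)")
    TRUE
})

#' Construct an F2TC parameter vector
#' @param F,K1 flow and influx rate (mL/min/g), `K1 <= F`.
#' @param W vascular window width (s).
#' @param k2,k3,k4 tissue rate constants (1/min).
#' @param t0 tissue bolus delay (s).
#' @return An [F2TCParams-class] object.
#' @export
F2TCParams <- function(F, W, K1, k2, k3, k4, t0 = 0)
    new("F2TCParams", F = F, W = W, K1 = K1, k2 = k2, k3 = k3, k4 = k4,
        t0 = t0)

#' Adiabatic tissue-homogeneity (Johnson-Wilson) parameters
#'
#' Impulse residue function: unity during the capillary transit `[T0, T0+Tc)`,
#' then an extracted fraction `E` washing out of the interstitial space of
#' volume `Ve` at rate `E*BF/Ve`.
#'
#' @slot BF blood flow, mL/min/100g
#' @slot Tc capillary (vascular) transit time, seconds
#' @slot E extraction fraction in `[0, 1)`
#' @slot Ve interstitial distribution volume, mL/100g
#' @slot T0 contrast arrival delay, seconds
#' @export
setClass("ATHParams",
         representation(BF = "numeric", Tc = "numeric", E = "numeric",
                        Ve = "numeric", T0 = "numeric"))

setValidity("ATHParams", function(object) {
    v <- c(object@BF, object@Tc, object@E, object@Ve, object@T0)
    if (length(v) != 5L || any(!is.finite(v))) return("all slots scalar finite")
    if (object@BF < 0 || object@Tc < 0 || object@T0 < 0)
        return("BF, Tc, T0 must be non-negative")
    if (object@E < 0 || object@E >= 1) return("E must lie in [0, 1)")
    if (object@E > 0 && object@Ve <= 0) return("Ve must be positive when E > 0")
    TRUE
})

#' Construct an ATH parameter vector
#' @param BF blood flow (mL/min/100g).
#' @param Tc capillary transit time (s).
#' @param E extraction fraction, `0 <= E < 1`.
#' @param Ve interstitial volume (mL/100g).
#' @param T0 arrival delay (s).
#' @return An [ATHParams-class] object.
#' @export
ATHParams <- function(BF, Tc, E, Ve = 15, T0 = 0)
    new("ATHParams", BF = BF, Tc = Tc, E = E, Ve = Ve, T0 = T0)

# ---------------------------------------------------------------------------
# Fit result

#' Result of a kinetic model fit
#'
#' @slot params the fitted parameter object ([F2TCParams-class] or
#'   [ATHParams-class])
#' @slot modality `"pet"` or `"ctp"`
#' @slot fitted fitted frame values
#' @slot residuals raw (unweighted) residuals
#' @slot rss weighted residual sum of squares of the best start
#' @slot converged logical; `FALSE` marks the parameters unreliable
#' @slot degenerate logical; `TRUE` for an all-zero input curve
#' @slot nStarts number of optimizer starts used
#' @export
setClass("KineticFit",
         representation(params = "ANY", modality = "character",
                        fitted = "numeric", residuals = "numeric",
                        rss = "numeric", converged = "logical",
                        degenerate = "logical", nStarts = "integer"))

setValidity("KineticFit", function(object) {
    if (!object@modality %in% c("pet", "ctp")) return("modality pet/ctp")
    if (any(!is.finite(object@residuals))) return("non-finite residuals")
    if (!is.finite(object@rss)) return("non-finite rss")
    TRUE
})

# ---------------------------------------------------------------------------
# Phantom study

#' One synthetic patient study
#'
#' Bundles everything one enrolled patient contributes: a labelled voxel grid
#' (0 background, 1 non-DIL prostate, 2 DIL), the dynamic PET and CTP volumes
#' with their schedules, the late SUV volume, the two arterial input curves,
#' and per-voxel ground-truth parameter maps.
#'
#' @slot patientId character identifier
#' @slot mask integer 3D array; 0 = background, 1 = non-DIL, 2 = DIL
#' @slot spacing numeric length-3 voxel spacing (mm)
#' @slot petDynamic 4D array (x, y, z, frame) of frame-mean activity (kBq/mL)
#' @slot petSchedule PET [FrameSchedule-class]
#' @slot ctpDynamic 4D array of CT enhancement frames
#' @slot ctpSchedule CTP [FrameSchedule-class]
#' @slot suvLate 3D array, 2-h post-injection SUV (g/mL)
#' @slot petAIF,ctpAIF sampled arterial input curves
#' @slot petAIFModel,ctpAIFModel the generating [AIFModel-class]s
#' @slot truthMaps named list of 3D arrays, one per parametric map
#' @slot dose injected activity (MBq)
#' @slot weight body weight (kg)
#' @slot seed integer seed the study was generated from
#' @export
setClass("PhantomStudy",
         representation(patientId = "character", mask = "array",
                        spacing = "numeric",
                        petDynamic = "array", petSchedule = "FrameSchedule",
                        ctpDynamic = "array", ctpSchedule = "FrameSchedule",
                        suvLate = "array",
                        petAIF = "TimeActivityCurve",
                        ctpAIF = "TimeActivityCurve",
                        petAIFModel = "AIFModel", ctpAIFModel = "AIFModel",
                        truthMaps = "list", dose = "numeric",
                        weight = "numeric", seed = "integer"))

setValidity("PhantomStudy", function(object) {
    if (!all(object@mask %in% 0:2)) return("mask labels must be 0/1/2")
    d <- dim(object@mask)
    if (length(d) != 3L) return("mask must be 3D")
    if (!identical(dim(object@petDynamic)[1:3], d))
        return("PET grid does not match mask")
    if (!identical(dim(object@ctpDynamic)[1:3], d))
        return("CTP grid does not match mask")
    if (!identical(dim(object@suvLate), d)) return("late SUV grid mismatch")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        return("spacing must be 3 positive numbers")
    TRUE
})

# ---------------------------------------------------------------------------
# Parametric map set

#' The 13 voxel-wise parametric maps of one patient
#'
#' @slot maps named list of 13 3D arrays (K1, k2, k3, k4, Ki, DV, SUVearly,
#'   SUVlate, BF, BV, MTT, PS, T0); background voxels are `NA`
#' @slot spacing voxel spacing (mm)
#' @slot converged logical 3D array, per-voxel joint convergence flag
#' @export
setClass("ParametricMapSet",
         representation(maps = "list", spacing = "numeric",
                        converged = "array"))

#' Canonical order of the 13 parametric maps
#' @return Character vector of map names.
#' @export
mapNames <- function()
    c("K1", "k2", "k3", "k4", "Ki", "DV", "SUVearly", "SUVlate",
      "BF", "BV", "MTT", "PS", "T0")

setValidity("ParametricMapSet", function(object) {
    if (!identical(sort(names(object@maps)), sort(mapNames())))
        return("maps must be exactly the 13 canonical parametric maps")
    d <- dim(object@maps[[1L]])
    if (!all(vapply(object@maps, function(m) identical(dim(m), d), logical(1))))
        return("all maps must share one grid")
    if (!identical(dim(object@converged), d))
        return("convergence array grid mismatch")
    TRUE
})

# ---------------------------------------------------------------------------
# Cross-validation report

#' Leave-one-patient-out cross-validation report
#'
#' @slot folds data.frame with one row per fold: patient, ER, FPR, FNR, AUC,
#'   Dice (NA where undefined)
#' @slot summary data.frame of mean, SD and SE per metric across folds
#' @slot model character descriptor of the classifier (feature names)
#' @slot threshold probability cut-off used for the hard classification
#' @export
setClass("CVReport",
         representation(folds = "data.frame", summary = "data.frame",
                        model = "character", threshold = "numeric"))

setValidity("CVReport", function(object) {
    rates <- unlist(object@folds[intersect(c("ER", "FPR", "FNR", "AUC"),
                                           names(object@folds))])
    rates <- rates[!is.na(rates)]
    if (length(rates) && (any(rates < 0) || any(rates > 1)))
        return("rates must lie in [0, 1]")
    TRUE
})
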