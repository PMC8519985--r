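# Generics and small accessors/show methods for the core classes.

#' Number of frames of a schedule
#' @param x a [FrameSchedule-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameSchedule", function(x) length(x@frameStart))

#' Frame start times (s)
#' @param x a [FrameSchedule-class]
#' @export
setGeneric("frameStart", function(x) standardGeneric("frameStart"))
#' @rdname frameStart
#' @export
setMethod("frameStart", "FrameSchedule", function(x) x@frameStart)

#' Frame end times (s)
#' @param x a [FrameSchedule-class]
#' @export
setGeneric("frameEnd", function(x) standardGeneric("frameEnd"))
#' @rdname frameEnd
#' @export
setMethod("frameEnd", "FrameSchedule", function(x) x@frameEnd)

#' Frame midpoints (s)
#' @param x a [FrameSchedule-class]
#' @export
setGeneric("frameMid", function(x) standardGeneric("frameMid"))
#' @rdname frameMid
#' @export
setMethod("frameMid", "FrameSchedule",
          function(x) (x@frameStart + x@frameEnd) / 2)

#' Frame durations (s)
#' @param x a [FrameSchedule-class]
#' @export
setGeneric("frameDuration", function(x) standardGeneric("frameDuration"))
#' @rdname frameDuration
#' @export
setMethod("frameDuration", "FrameSchedule",
          function(x) x@frameEnd - x@frameStart)

setMethod("show", "FrameSchedule", function(object) {
    cat(sprintf("FrameSchedule: %d frames spanning [%g, %g] s\n",
                nFrames(object), object@frameStart[1L],
                object@frameEnd[nFrames(object)]))
    d <- frameDuration(object)
    rl <- rle(d)
    cat("  durations:",
        paste(sprintf("%d x %g s", rl$lengths, rl$values), collapse = ", "),
        "\n")
})

#' Sample times of a curve (s)
#' @param x a [TimeActivityCurve-class]
#' @export
setGeneric("curveTime", function(x) standardGeneric("curveTime"))
#' @rdname curveTime
#' @export
setMethod("curveTime", "TimeActivityCurve", function(x) x@time)

#' Sample values of a curve
#' @param x a [TimeActivityCurve-class]
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @rdname curveValues
#' @export
setMethod("curveValues", "TimeActivityCurve", function(x) x@activity)

setMethod("show", "TimeActivityCurve", function(object) {
    cat(sprintf("TimeActivityCurve: %d samples on [%g, %g] s, peak %.4g %s\n",
                length(object@time),
                if (length(object@time)) object@time[1L] else NA,
                if (length(object@time)) object@time[length(object@time)] else NA,
                if (length(object@activity)) max(object@activity) else NA,
                object@units))
})

#' @export
#' @method as.data.frame TimeActivityCurve
as.data.frame.TimeActivityCurve <- function(x, ...)
    data.frame(time_s = x@time, value = x@activity)

setMethod("show", "AIFModel", function(object) {
    cat(sprintf("AIFModel <%s>, delay %g s\n", object@model, object@delay))
    print(round(object@params, 5))
})

setMethod("show", "F2TCParams", function(object) {
    cat(sprintf(
        "F2TCParams: F=%.4g mL/min/g, W=%.3g s, K1=%.4g mL/min/g,\n  k2=%.4g, k3=%.4g, k4=%.4g 1/min, t0=%.3g s (Ki=%.4g, DV=%s)\n",
        object@F, object@W, object@K1, object@k2, object@k3, object@k4,
        object@t0, kiOf(object),
        tryCatch(sprintf("%.4g", dvOf(object)), error = function(e) "undef")))
})

setMethod("show", "ATHParams", function(object) {
    cat(sprintf(
        "ATHParams: BF=%.4g mL/min/100g, Tc=%.3g s, E=%.4g, Ve=%.3g mL/100g, T0=%.3g s\n  (BV=%.4g mL/100g, MTT=%.3g s, PS=%.4g mL/min/100g)\n",
        object@BF, object@Tc, object@E, object@Ve, object@T0,
        bvOf(object@BF, object@Tc), object@Tc, psOf(object@BF, object@E)))
})

#' Extract the fitted parameter object from a kinetic fit
#' @param x a [KineticFit-class]
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname fitParams
#' @export
setMethod("fitParams", "KineticFit", function(x) x@params)

#' Did the fit converge?
#' @param x a [KineticFit-class]
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname isConverged
#' @export
setMethod("isConverged", "KineticFit", function(x) x@converged)

setMethod("show", "KineticFit", function(object) {
    cat(sprintf("KineticFit [%s]: rss=%.4g, converged=%s%s, %d starts\n",
                object@modality, object@rss, object@converged,
                if (object@degenerate) " (degenerate input)" else "",
                object@nStarts))
    show(object@params)
})

setMethod("show", "PhantomStudy", function(object) {
    d <- dim(object@mask)
    cat(sprintf(
        "PhantomStudy '%s': grid %dx%dx%d (%g x %g x %g mm), %d prostate voxels (%d DIL)\n",
        object@patientId, d[1], d[2], d[3], object@spacing[1],
        object@spacing[2], object@spacing[3], sum(object@mask > 0),
        sum(object@mask == 2)))
    cat(sprintf("  PET: %d frames; CTP: %d frames; seed %d\n",
                nFrames(object@petSchedule), nFrames(object@ctpSchedule),
                object@seed))
})

#' Access one parametric map
#' @param x a [ParametricMapSet-class]
#' @param name one of [mapNames()]
#' @return 3D numeric array (`NA` outside the prostate)
#' @export
setGeneric("getMap", function(x, name) standardGeneric("getMap"))
#' @rdname getMap
#' @export
setMethod("getMap", "ParametricMapSet", function(x, name) {
    if (!name %in% names(x@maps)) stop("unknown map: ", name)
    x@maps[[name]]
})

setMethod("show", "ParametricMapSet", function(object) {
    d <- dim(object@maps[[1L]])
    cat(sprintf("ParametricMapSet: %d maps on %dx%dx%d grid, %d fitted voxels (%d converged)\n",
                length(object@maps), d[1], d[2], d[3],
                sum(!is.na(object@maps[[1L]])),
                sum(object@converged, na.rm = TRUE)))
})

#' Per-fold metric table of a CV report
#' @param x a [CVReport-class]
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))
#' @rdname cvFolds
#' @export
setMethod("cvFolds", "CVReport", function(x) x@folds)

#' Summary (mean/SD/SE per metric) of a CV report
#' @param x a [CVReport-class]
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))
#' @rdname cvSummary
#' @export
setMethod("cvSummary", "CVReport", function(x) x@summary)

setMethod("show", "CVReport", function(object) {
    cat(sprintf("CVReport [%s], %d folds, threshold %.2f\n", object@model,
                nrow(object@folds), object@threshold))
    print(object@summary, row.names = FALSE, digits = 4)
})
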