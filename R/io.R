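# File I/O at the artifact boundaries: NIfTI volumes, 2-column CSV curves,
# JSON fit results / CV reports, YAML study configuration.

#' Write a volume (3D/4D array) as NIfTI-1
#'
#' @param vol numeric or integer array (3D, or 4D for dynamic data).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm (length 3).
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path, spacing = c(1, 1, 1)) {
    img <- RNifti::asNifti(vol)
    pd <- spacing
    if (length(dim(vol)) == 4L) pd <- c(spacing, 1)
    img <- RNifti::`pixdim<-`(img, pd)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file path.
#' @return List with `data` (array) and `spacing` (mm, length 3).
#' @export
readVolume <- function(path) {
    img <- RNifti::readNifti(path)
    list(data = array(as.numeric(img), dim(img)),
         spacing = RNifti::pixdim(img)[1:3])
}

#' Check that volumes of one study share a grid
#'
#' @param ... lists as returned by [readVolume()] (or arrays).
#' @return Invisibly `TRUE`; error on any spatial-grid or spacing mismatch.
#' @export
checkSameGrid <- function(...) {
    vols <- list(...)
    dims <- lapply(vols, function(v) {
        d <- if (is.list(v)) dim(v$data) else dim(v)
        d[1:3]
    })
    if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
        stop("spatial grid mismatch across the study's volumes")
    sp <- lapply(vols, function(v) if (is.list(v)) v$spacing else NULL)
    sp <- sp[!vapply(sp, is.null, logical(1))]
    if (length(sp) > 1L &&
        !all(vapply(sp, function(s) isTRUE(all.equal(s, sp[[1L]])),
                    logical(1))))
        stop("voxel spacing mismatch across the study's volumes")
    invisible(TRUE)
}

#' Write a time-activity curve as 2-column CSV
#'
#' Columns `time_s, value`.
#' @param tac a [TimeActivityCurve-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeTAC <- function(tac, path) {
    write.csv(as.data.frame(tac), path, row.names = FALSE)
    invisible(path)
}

#' Read a 2-column CSV time-activity curve
#'
#' @param path CSV with columns `time_s, value`.
#' @param units unit label to attach.
#' @return A [TimeActivityCurve-class].
#' @export
readTAC <- function(path, units = "a.u.") {
    df <- read.csv(path)
    if (!all(c("time_s", "value") %in% names(df)))
        stop("expected columns time_s, value")
    TimeActivityCurve(df$time_s, df$value, units)
}

#' Serialize a kinetic fit as JSON
#'
#' @param fit a [KineticFit-class].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeFitResult <- function(fit, path) {
    p <- fit@params
    pars <- if (is(p, "F2TCParams"))
        list(F = p@F, W = p@W, K1 = p@K1, k2 = p@k2, k3 = p@k3, k4 = p@k4,
             t0 = p@t0, Ki = kiOf(p), DV = suppressWarnings(dvOf(p)))
    else list(BF = p@BF, Tc = p@Tc, E = p@E, Ve = p@Ve, T0 = p@T0,
              BV = bvOf(p@BF, p@Tc), MTT = p@Tc, PS = psOf(p@BF, p@E))
    jsonlite::write_json(
        list(modality = fit@modality, params = pars, rss = fit@rss,
             converged = fit@converged, degenerate = fit@degenerate,
             nStarts = fit@nStarts),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}

#' Write a parametric map set (one NIfTI per map + JSON manifest)
#'
#' @param mapSet a [ParametricMapSet-class].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return The manifest path, invisibly.
#' @export
writeMapSet <- function(mapSet, dir, prefix = "map") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(mapNames(), function(nm) {
        f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
        writeVolume(getMap(mapSet, nm), f, mapSet@spacing)
        basename(f)
    }, character(1))
    manifest <- file.path(dir, sprintf("%s_manifest.json", prefix))
    jsonlite::write_json(
        list(maps = as.list(files), spacing = mapSet@spacing,
             nConverged = sum(mapSet@converged, na.rm = TRUE)),
        manifest, auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

#' Write a cross-validation report as JSON and CSV
#'
#' @param report a [CVReport-class].
#' @param path base path without extension; writes `<path>.json` and
#'   `<path>.csv` (the per-fold table).
#' @return The JSON path, invisibly.
#' @export
writeCVReport <- function(report, path) {
    write.csv(cvFolds(report), paste0(path, ".csv"), row.names = FALSE)
    jsonlite::write_json(
        list(model = report@model, threshold = report@threshold,
             folds = cvFolds(report), summary = cvSummary(report)),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
    invisible(paste0(path, ".json"))
}
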