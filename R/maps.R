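# Voxel-wise orchestration: pre-fit TAC smoothing and production of the 13
# parametric maps of one patient, plus the flat voxel table the statistical
# machinery consumes.

# 3x3 in-plane mean with a kernel that shrinks at the image border
smooth2D <- function(m) {
    n <- matrix(0, nrow(m), ncol(m))
    cnt <- matrix(0, nrow(m), ncol(m))
    nr <- nrow(m); nc <- ncol(m)
    for (di in -1:1) for (dj in -1:1) {
        ri <- max(1, 1 + di):min(nr, nr + di)
        rj <- max(1, 1 + dj):min(nc, nc + dj)
        si <- ri - di; sj <- rj - dj
        n[ri, rj] <- n[ri, rj] + m[si, sj]
        cnt[ri, rj] <- cnt[ri, rj] + 1
    }
    n / cnt
}

#' In-slice 3x3 mean smoothing of a dynamic volume
#'
#' Replaces each voxel's frame value by the mean over its 3x3 in-slice
#' neighbourhood (no mixing across slices). At edges the kernel shrinks to
#' the available in-slice neighbours, so a corner voxel averages its 4-member
#' neighbourhood.
#'
#' @param vol 4D array (x, y, z, frame) — a 3D array is treated as one frame.
#' @return Array of the same shape.
#' @export
smoothTac3x3 <- function(vol) {
    d <- dim(vol)
    if (length(d) == 3L) { vol <- array(vol, c(d, 1L)); d <- dim(vol) }
    if (length(d) != 4L) stop("expected a 3D or 4D volume")
    out <- vol
    for (z in seq_len(d[3])) for (f in seq_len(d[4]))
        out[, , z, f] <- smooth2D(vol[, , z, f])
    out
}

#' Build the 13 parametric maps of one phantom study
#'
#' Smooths the dynamic PET volume (3x3 in-slice mean, unless
#' `opts$smooth = FALSE`), then per prostate voxel fits the F2TC model to the
#' PET TAC and the ATH model to the CTP curve, computes Ki and DV from the
#' fitted vectors, SUV_Early from the late dynamic frames and takes SUV_Late
#' from the study's late volume. Background voxels are `NA` in every map;
#' per-voxel non-convergence is recorded in the flag array, never aborts.
#'
#' @param study a [PhantomStudy-class].
#' @param opts list: `smooth` (default `TRUE`), plus `nStarts`, `seed`,
#'   `dt` (PET grid, 0.5 s) and `dtCtp` (CTP grid, 0.1 s) forwarded to the
#'   fitters.
#' @return A [ParametricMapSet-class].
#' @export
buildMaps <- function(study, opts = list()) {
    stopifnot(is(study, "PhantomStudy"))
    smooth <- opts$smooth %||% TRUE
    petOpts <- list(nStarts = opts$nStarts %||% 5L,
                    seed = opts$seed %||% 1L, dt = opts$dt %||% 0.5)
    ctpOpts <- list(nStarts = petOpts$nStarts, seed = petOpts$seed,
                    dt = opts$dtCtp %||% 0.1)
    pet <- if (smooth) smoothTac3x3(study@petDynamic) else study@petDynamic
    ctp <- study@ctpDynamic
    petSch <- study@petSchedule; ctpSch <- study@ctpSchedule
    dims <- dim(study@mask)

    maps <- setNames(lapply(mapNames(), function(x) array(NA_real_, dims)),
                     mapNames())
    conv <- array(NA, dims)
    vox <- which(study@mask > 0L)
    for (v in vox) {
        k <- arrayInd(v, dims)
        tacP <- TimeActivityCurve(frameMid(petSch),
                                  pmax(pet[k[1], k[2], k[3], ], 0))
        fitP <- fitF2TC(tacP, study@petAIFModel, petSch, petOpts)
        p <- fitParams(fitP)
        maps$K1[v] <- p@K1; maps$k2[v] <- p@k2
        maps$k3[v] <- p@k3; maps$k4[v] <- p@k4
        maps$Ki[v] <- kiOf(p)
        maps$DV[v] <- suppressWarnings(dvOf(p))
        maps$SUVearly[v] <- suvEarly(tacP, petSch, study@dose, study@weight)
        maps$SUVlate[v] <- study@suvLate[v]

        tacC <- TimeActivityCurve(frameMid(ctpSch),
                                  pmax(ctp[k[1], k[2], k[3], ], 0))
        fitC <- fitATH(tacC, study@ctpAIFModel, ctpSch, ctpOpts)
        a <- fitParams(fitC)
        maps$BF[v] <- a@BF; maps$BV[v] <- bvOf(a@BF, a@Tc)
        maps$MTT[v] <- a@Tc; maps$PS[v] <- psOf(a@BF, a@E)
        maps$T0[v] <- a@T0
        conv[v] <- isConverged(fitP) && isConverged(fitC)
    }
    new("ParametricMapSet", maps = maps, spacing = study@spacing,
        converged = conv)
}

#' Pool per-voxel map values of a cohort into a voxel table
#'
#' One row per prostate voxel: patient id, voxel indices, the DIL label
#' (1 = DIL, 0 = non-DIL) and the 13 parametric map values. Rows with any
#' missing value (e.g. undefined DV in a voxel whose fitted k4 is zero) are
#' dropped so the retained table is complete.
#'
#' @param studies list of [PhantomStudy-class]s.
#' @param mapSets matching list of [ParametricMapSet-class]s (default: built
#'   with [buildMaps()] per study).
#' @param opts options forwarded to [buildMaps()] when `mapSets` is `NULL`.
#' @return A voxel table `data.frame` with columns `patient`, `i`, `j`, `k`,
#'   `label` and the 13 maps.
#' @export
buildVoxelTable <- function(studies, mapSets = NULL, opts = list()) {
    if (is.null(mapSets)) mapSets <- lapply(studies, buildMaps, opts = opts)
    stopifnot(length(studies) == length(mapSets))
    rows <- lapply(seq_along(studies), function(s) {
        study <- studies[[s]]; ms <- mapSets[[s]]
        vox <- which(study@mask > 0L)
        k <- arrayInd(vox, dim(study@mask))
        vals <- vapply(mapNames(), function(nm) getMap(ms, nm)[vox],
                       numeric(length(vox)))
        df <- data.frame(patient = study@patientId, i = k[, 1], j = k[, 2],
                         k = k[, 3],
                         label = as.integer(study@mask[vox] == 2L))
        cbind(df, as.data.frame(vals))
    })
    tab <- do.call(rbind, rows)
    tab[complete.cases(tab), , drop = FALSE]
}

#' Validate a voxel table
#'
#' Checks the contract of the flat per-voxel table: a `patient` column, a
#' binary `label` column with both classes present across at least two
#' patients, and complete numeric feature columns.
#'
#' @param table a voxel table `data.frame`.
#' @param features feature columns that must be present (default: the 13
#'   maps intersected with the table's columns).
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validateVoxelTable <- function(table, features = NULL) {
    if (!is.data.frame(table)) stop("voxel table must be a data.frame")
    if (!all(c("patient", "label") %in% names(table)))
        stop("voxel table needs 'patient' and 'label' columns")
    if (is.null(features)) features <- intersect(mapNames(), names(table))
    if (!length(features)) stop("no feature columns present")
    miss <- setdiff(features, names(table))
    if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
    if (!all(table$label %in% c(0L, 1L))) stop("label must be 0/1")
    if (length(unique(table$label)) < 2L) stop("both classes must be present")
    if (length(unique(table$patient)) < 2L) stop("need at least 2 patients")
    if (any(!is.finite(as.matrix(table[features]))))
        stop("feature columns contain missing values")
    invisible(TRUE)
}
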