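# Digital-phantom generator: tissue class specifications, study geometry,
# single-study and cohort simulation, and a parameter-space cohort sampler
# for the statistical machinery.

#' Tissue class specification for phantom simulation
#'
#' Generating kinetics of one tissue class (DIL or non-DIL): the F2TC and ATH
#' reference parameter vectors, the target late (2-h) SUV median the late
#' volume is scaled to, and the log-normal per-voxel parameter spread
#' (`sdlog`; 0 makes every voxel of the class identical).
#'
#' @slot label `"DIL"` or `"non-DIL"`
#' @slot f2tc an [F2TCParams-class]
#' @slot ath an [ATHParams-class]
#' @slot suvLateTarget target class-median SUV_Late, g/mL
#' @slot voxelJitter log-normal sdlog of per-voxel parameter spread
#' @export
setClass("TissueClassSpec",
         representation(label = "character", f2tc = "F2TCParams",
                        ath = "ATHParams", suvLateTarget = "numeric",
                        voxelJitter = "numeric"))

setValidity("TissueClassSpec", function(object) {
    if (object@voxelJitter < 0) return("voxelJitter must be >= 0")
    if (object@suvLateTarget < 0) return("suvLateTarget must be >= 0")
    TRUE
})

#' Default DIL tissue specification
#'
#' Reference kinetics of [dilReferenceF2TC()] / [dilReferenceATH()] with a
#' late-SUV target of 1.55 g/mL (the DIL median).
#'
#' @param voxelJitter per-voxel log-normal parameter spread (sdlog);
#'   default 0.15.
#' @return A [TissueClassSpec-class].
#' @export
dilTissueSpec <- function(voxelJitter = 0.15)
    new("TissueClassSpec", label = "DIL", f2tc = dilReferenceF2TC(),
        ath = dilReferenceATH(), suvLateTarget = 1.55,
        voxelJitter = voxelJitter)

#' Default non-DIL tissue specification
#'
#' Reference kinetics of [nondilReferenceF2TC()] / [nondilReferenceATH()]
#' with a late-SUV target of 0.67 g/mL (the non-DIL median).
#'
#' @inheritParams dilTissueSpec
#' @return A [TissueClassSpec-class].
#' @export
nondilTissueSpec <- function(voxelJitter = 0.15)
    new("TissueClassSpec", label = "non-DIL", f2tc = nondilReferenceF2TC(),
        ath = nondilReferenceATH(), suvLateTarget = 0.67,
        voxelJitter = voxelJitter)

#' Phantom study geometry
#'
#' A rectangular prostate block of `dim` voxels (default 20 x 20 x 8 at
#' 2 x 2 x 3.27 mm) padded by `pad` background voxels on every side, with an
#' off-centre ellipsoidal DIL occupying roughly `dilFrac` of the prostate.
#'
#' @param dim integer length-3, prostate block in voxels.
#' @param spacing voxel spacing in mm.
#' @param dilFrac target DIL fraction of prostate voxels.
#' @param pad background padding in voxels.
#' @return A named list consumed by [simulateStudy()].
#' @export
phantomGeometry <- function(dim = c(20L, 20L, 8L),
                            spacing = c(2, 2, 3.27),
                            dilFrac = 0.12, pad = 1L) {
    stopifnot(length(dim) == 3L, all(dim >= 2L), length(spacing) == 3L,
              all(spacing > 0), dilFrac > 0, dilFrac < 1, pad >= 0L)
    list(dim = as.integer(dim), spacing = as.numeric(spacing),
         dilFrac = dilFrac, pad = as.integer(pad))
}

# label mask from a geometry: 0 background, 1 non-DIL, 2 DIL
buildMask <- function(geom) {
    d <- geom$dim; pad <- geom$pad
    full <- d + 2L * pad
    mask <- array(0L, full)
    mask[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- 1L

    # ellipsoid semi-axes (voxels) giving ~ dilFrac of the prostate volume,
    # z-axis shortened to respect the thinner slab
    target <- geom$dilFrac * prod(d)
    a <- (target * 3 / (4 * pi * 0.8))^(1 / 3)
    ax <- c(a, a, 0.8 * a)
    ctr <- pad + c(0.35, 0.5, 0.5) * d
    if (any(ax >= d / 2 + 0.5))
        stop("DIL region does not fit inside the prostate block")
    idx <- which(mask == 1L, arr.ind = TRUE)
    r2 <- ((idx[, 1] - ctr[1]) / ax[1])^2 + ((idx[, 2] - ctr[2]) / ax[2])^2 +
        ((idx[, 3] - ctr[3]) / ax[3])^2
    mask[idx[r2 <= 1, , drop = FALSE]] <- 2L
    mask
}

# one log-normal jitter factor per named parameter
jitterFactors <- function(names, sdlog) {
    f <- setNames(rep(1, length(names)), names)
    if (sdlog > 0) f[] <- rlnorm(length(names), 0, sdlog)
    f
}

# apply multiplicative factors to the class reference vectors; K1 follows F
# (fixed extraction) and E is recomputed from jittered PS and BF so the
# physical constraints K1 <= F and E < 1 survive any jitter
jitterSpec <- function(spec, f) {
    p <- spec@f2tc
    pet <- F2TCParams(F = p@F * f[["K1"]], W = p@W, K1 = p@K1 * f[["K1"]],
                      k2 = p@k2 * f[["k2"]], k3 = p@k3 * f[["k3"]],
                      k4 = p@k4 * f[["k4"]], t0 = p@t0)
    a <- spec@ath
    ps <- psOf(a@BF, a@E) * f[["PS"]]
    bf <- a@BF * f[["BF"]]
    ath <- ATHParams(BF = bf, Tc = a@Tc * f[["Tc"]],
                     E = 1 - exp(-ps / bf), Ve = a@Ve, T0 = a@T0)
    list(f2tc = pet, ath = ath)
}

jitterNames <- c("K1", "k2", "k3", "k4", "BF", "Tc", "PS")

# frame-weighted Gaussian noise, clamped at zero
addFrameNoise <- function(values, durations, noiseScale) {
    if (noiseScale == 0) return(values)
    sdv <- noiseScale * sqrt(pmax(values, 0) / durations)
    pmax(values + rnorm(length(values), 0, sdv), 0)
}

lateWindow <- function() FrameSchedule(7200, 8100)   # 120-135 min

#' Simulate one phantom patient study
#'
#' Builds the labelled voxel grid, draws per-voxel ground-truth kinetic
#' parameters around each class reference (log-normal spread per class
#' specification), and synthesizes the dynamic PET volume (frame-averaged
#' F2TC forward model), the CT-perfusion volume (ATH forward model) and the
#' late SUV volume (forward model over the 120-135 min window, scaled to the
#' class late-SUV target). Frame noise is mean-zero Gaussian with SD
#' `noiseScale * sqrt(value / duration)`, clamped at zero. With
#' `noiseScale = 0` and zero voxel jitter every voxel reproduces the class
#' forward model exactly.
#'
#' @param dilSpec,nondilSpec [TissueClassSpec-class]s of the two classes.
#' @param geometry a [phantomGeometry()] list.
#' @param noiseScale noise magnitude (>= 0), default 0.2.
#' @param seed integer seed; identical seeds reproduce the study bit-for-bit.
#' @param patientId identifier stored in the study.
#' @param dose,weight injected activity (MBq) and body weight (kg).
#' @return A [PhantomStudy-class].
#' @examples
#' st <- simulateStudy(geometry = phantomGeometry(dim = c(6, 6, 2)),
#'                     noiseScale = 0, seed = 1)
#' st
#' @export
simulateStudy <- function(dilSpec = dilTissueSpec(),
                          nondilSpec = nondilTissueSpec(),
                          geometry = phantomGeometry(),
                          noiseScale = 0.2, seed = 1L,
                          patientId = sprintf("P%03d", seed),
                          dose = cohortDefaults()$dose,
                          weight = cohortDefaults()$weight) {
    stopifnot(is(dilSpec, "TissueClassSpec"), is(nondilSpec, "TissueClassSpec"))
    if (noiseScale < 0) stop("noiseScale must be >= 0")
    withSeed(seed, {
        mask <- buildMask(geometry)
        petSch <- petFrameSchedule()
        ctpSch <- ctpFrameSchedule()
        petAIF <- petDefaultAIF()
        ctpAIF <- ctpDefaultAIF()

        faPet <- fineAIF(petAIF, max(frameEnd(petSch)))
        faCtp <- fineAIF(ctpAIF, max(frameEnd(ctpSch)), dt = 0.1)
        faLate <- fineAIF(petAIF, 8100, dt = 2)
        lateSch <- lateWindow()

        # class scaling so the class reference hits its late-SUV target
        lateScale <- function(spec) {
            ref <- .f2tc_frame_conv(
                c(spec@f2tc@F, spec@f2tc@W, spec@f2tc@K1, spec@f2tc@k2,
                  spec@f2tc@k3, spec@f2tc@k4, spec@f2tc@t0),
                faLate$A, faLate$dt, frameStart(lateSch), frameEnd(lateSch))
            if (ref <= 0) return(0)
            spec@suvLateTarget / suv(ref, dose, weight)
        }
        scales <- list(`1` = lateScale(nondilSpec), `2` = lateScale(dilSpec))

        dims <- dim(mask)
        nPet <- nFrames(petSch); nCtp <- nFrames(ctpSch)
        petVol <- array(0, c(dims, nPet))
        ctpVol <- array(0, c(dims, nCtp))
        lateVol <- array(0, dims)
        truth <- setNames(lapply(mapNames(),
                                 function(x) array(NA_real_, dims)),
                          mapNames())

        vox <- which(mask > 0L)
        petDur <- frameDuration(petSch); ctpDur <- frameDuration(ctpSch)
        for (v in vox) {
            spec <- if (mask[v] == 2L) dilSpec else nondilSpec
            pr <- jitterSpec(spec, jitterFactors(jitterNames, spec@voxelJitter))
            p <- pr$f2tc; a <- pr$ath
            thP <- c(p@F, p@W, p@K1, p@k2, p@k3, p@k4, p@t0)
            tacP <- .f2tc_frame_conv(thP, faPet$A, faPet$dt,
                                     frameStart(petSch), frameEnd(petSch))
            tacC <- .ath_frame_conv(c(a@BF, a@Tc, a@E, a@Ve, a@T0),
                                    faCtp$A, faCtp$dt,
                                    frameStart(ctpSch), frameEnd(ctpSch))
            lateAct <- .f2tc_frame_conv(thP, faLate$A, faLate$dt,
                                        frameStart(lateSch),
                                        frameEnd(lateSch))
            noisyP <- addFrameNoise(tacP, petDur, noiseScale)
            noisyC <- addFrameNoise(tacC, ctpDur, noiseScale)
            noisyL <- addFrameNoise(lateAct, 900, noiseScale)

            k <- arrayInd(v, dims)
            petVol[k[1], k[2], k[3], ] <- noisyP
            ctpVol[k[1], k[2], k[3], ] <- noisyC
            sLate <- scales[[as.character(mask[v])]]
            lateVol[v] <- suv(noisyL, dose, weight) * sLate

            truth$K1[v] <- p@K1; truth$k2[v] <- p@k2
            truth$k3[v] <- p@k3; truth$k4[v] <- p@k4
            truth$Ki[v] <- kiOf(p); truth$DV[v] <- dvOf(p)
            truth$SUVearly[v] <- suvEarly(
                TimeActivityCurve(frameMid(petSch), tacP), petSch, dose,
                weight)
            truth$SUVlate[v] <- suv(lateAct, dose, weight) * sLate
            truth$BF[v] <- a@BF; truth$BV[v] <- bvOf(a@BF, a@Tc)
            truth$MTT[v] <- a@Tc; truth$PS[v] <- psOf(a@BF, a@E)
            truth$T0[v] <- a@T0
        }

        new("PhantomStudy", patientId = patientId, mask = mask,
            spacing = geometry$spacing,
            petDynamic = petVol, petSchedule = petSch,
            ctpDynamic = ctpVol, ctpSchedule = ctpSch,
            suvLate = lateVol,
            petAIF = makeAIF(petAIF, seq(0, max(frameEnd(petSch)), by = 0.5)),
            ctpAIF = makeAIF(ctpAIF, seq(0, max(frameEnd(ctpSch)), by = 0.5)),
            petAIFModel = petAIF, ctpAIFModel = ctpAIF,
            truthMaps = truth, dose = dose, weight = weight,
            seed = as.integer(seed))
    })
}

#' Simulate a multi-patient phantom cohort
#'
#' One [simulateStudy()] per patient with per-patient multiplicative
#' log-normal jitter of the class reference parameters (the same factor for
#' both classes of a patient, preserving within-patient class contrast, as a
#' patient-level physiological effect).
#'
#' @param nPatients number of patients (>= 2), default 15.
#' @param dilSpec,nondilSpec class specifications.
#' @param geometry a [phantomGeometry()] list.
#' @param noiseScale frame noise magnitude.
#' @param seeds integer vector of per-patient seeds (at least `nPatients`).
#' @param patientJitter sdlog of the per-patient parameter jitter
#'   (default 0.1; 0 makes all patients share the reference values).
#' @return A list of [PhantomStudy-class] objects.
#' @export
makeCohort <- function(nPatients = 15L, dilSpec = dilTissueSpec(),
                       nondilSpec = nondilTissueSpec(),
                       geometry = phantomGeometry(), noiseScale = 0.2,
                       seeds = seq_len(nPatients), patientJitter = 0.1) {
    if (nPatients < 2L) stop("need at least 2 patients")
    if (length(seeds) < nPatients) stop("fewer seeds than patients")
    lapply(seq_len(nPatients), function(i) {
        f <- withSeed(seeds[i] + 10000L,
                      jitterFactors(jitterNames, patientJitter))
        dil <- jitterSpec(dilSpec, f)
        non <- jitterSpec(nondilSpec, f)
        dSpec <- new("TissueClassSpec", label = "DIL", f2tc = dil$f2tc,
                     ath = dil$ath, suvLateTarget = dilSpec@suvLateTarget,
                     voxelJitter = dilSpec@voxelJitter)
        nSpec <- new("TissueClassSpec", label = "non-DIL", f2tc = non$f2tc,
                     ath = non$ath, suvLateTarget = nondilSpec@suvLateTarget,
                     voxelJitter = nondilSpec@voxelJitter)
        simulateStudy(dSpec, nSpec, geometry, noiseScale, seeds[i],
                      patientId = sprintf("P%03d", i))
    })
}

# ---------------------------------------------------------------------------
# parameter-space cohort

referenceRow <- function(class = c("DIL", "non-DIL")) {
    class <- match.arg(class)
    if (class == "DIL") {
        p <- dilReferenceF2TC(); a <- dilReferenceATH()
        sEarly <- 2.53; sLate <- 1.55
    } else {
        p <- nondilReferenceF2TC(); a <- nondilReferenceATH()
        sEarly <- 1.78; sLate <- 0.67
    }
    c(K1 = p@K1, k2 = p@k2, k3 = p@k3, k4 = p@k4, Ki = kiOf(p),
      DV = dvOf(p), SUVearly = sEarly, SUVlate = sLate, BF = a@BF,
      BV = bvOf(a@BF, a@Tc), MTT = a@Tc, PS = psOf(a@BF, a@E), T0 = a@T0)
}

#' Sample a voxel table directly in parameter space
#'
#' Draws the 13-column per-voxel parameter table around the class reference
#' medians without running the imaging forward models: per-patient
#' multiplicative log-normal jitter (shared by both classes of a patient)
#' times independent per-voxel log-normal spread. Class contrast can be
#' restricted to a named subset of maps — the remaining columns use the
#' pooled (non-DIL) reference for both classes — which is how cohorts with
#' contrast confined to, say, Ki and k4 are constructed (confining contrast
#' through the physical forward model is impossible, since perturbing
#' k3/k4 moves DV and the SUV maps too).
#'
#' @param nPatients patients in the cohort, default 15.
#' @param voxelsPerPatient prostate voxels per patient, default 3284 (so a
#'   15-patient cohort pools about 49,000 voxels).
#' @param dilFrac fraction of DIL voxels per patient.
#' @param contrast character vector of map names carrying class contrast
#'   (default: all 13).
#' @param voxelSD per-voxel log-normal sdlog, default 0.25.
#' @param patientJitter per-patient log-normal sdlog, default 0.1.
#' @param seed integer master seed.
#' @return A voxel table `data.frame`: `patient`, `label` (1 = DIL), and the
#'   13 parameter columns (see [mapNames()]).
#' @export
simulateVoxelCohort <- function(nPatients = 15L, voxelsPerPatient = 3284L,
                                dilFrac = 0.12, contrast = mapNames(),
                                voxelSD = 0.25, patientJitter = 0.1,
                                seed = 1L) {
    stopifnot(nPatients >= 2L, voxelsPerPatient >= 2L,
              dilFrac > 0, dilFrac < 1)
    bad <- setdiff(contrast, mapNames())
    if (length(bad)) stop("unknown map names: ", paste(bad, collapse = ", "))
    dil <- referenceRow("DIL"); non <- referenceRow("non-DIL")
    dilRow <- non
    dilRow[contrast] <- dil[contrast]
    nm <- mapNames()
    withSeed(seed, {
        out <- vector("list", nPatients)
        nDil <- max(1L, round(dilFrac * voxelsPerPatient))
        for (i in seq_len(nPatients)) {
            pf <- rlnorm(length(nm), 0, patientJitter)
            lab <- c(rep(1L, nDil), rep(0L, voxelsPerPatient - nDil))
            base <- rbind(matrix(dilRow * pf, nDil, length(nm), byrow = TRUE),
                          matrix(non * pf, voxelsPerPatient - nDil,
                                 length(nm), byrow = TRUE))
            noise <- matrix(rlnorm(length(base), 0, voxelSD), nrow(base))
            tab <- as.data.frame(base * noise)
            names(tab) <- nm
            out[[i]] <- cbind(patient = sprintf("P%03d", i), label = lab, tab)
        }
        do.call(rbind, out)
    })
}
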