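# Digital phantom generator: determinism, noiseless exactness, masks,
# noise behaviour, cohorts and the parameter-space sampler.

test_that("identical seeds reproduce a study bit-for-bit", {
    g <- tinyGeom()
    a <- simulateStudy(geometry = g, noiseScale = 0.3, seed = 42L)
    b <- simulateStudy(geometry = g, noiseScale = 0.3, seed = 42L)
    expect_identical(a@petDynamic, b@petDynamic)
    expect_identical(a@ctpDynamic, b@ctpDynamic)
    expect_identical(a@suvLate, b@suvLate)
    expect_identical(a@truthMaps, b@truthMaps)
    c2 <- simulateStudy(geometry = g, noiseScale = 0.3, seed = 43L)
    expect_false(identical(a@petDynamic, c2@petDynamic))
})

test_that("with zero noise and zero voxel spread every voxel equals the
           class forward model exactly", {
    st <- simulateStudy(dilTissueSpec(0), nondilTissueSpec(0),
                        geometry = tinyGeom(), noiseScale = 0, seed = 1L)
    sch <- st@petSchedule
    dilTac <- curveValues(f2tcForward(dilReferenceF2TC(), st@petAIFModel,
                                      sch))
    nonTac <- curveValues(f2tcForward(nondilReferenceF2TC(),
                                      st@petAIFModel, sch))
    vDil <- which(st@mask == 2L, arr.ind = TRUE)[1, ]
    vNon <- which(st@mask == 1L, arr.ind = TRUE)[1, ]
    expect_equal(st@petDynamic[vDil[1], vDil[2], vDil[3], ], dilTac,
                 tolerance = 1e-12)
    expect_equal(st@petDynamic[vNon[1], vNon[2], vNon[3], ], nonTac,
                 tolerance = 1e-12)
    ctpDil <- curveValues(athForward(dilReferenceATH(), st@ctpAIFModel,
                                     st@ctpSchedule))
    expect_equal(st@ctpDynamic[vDil[1], vDil[2], vDil[3], ], ctpDil,
                 tolerance = 1e-12)
    # late volume hits the class SUV_Late targets exactly at zero noise
    expect_equal(st@suvLate[vDil[1], vDil[2], vDil[3]], 1.55,
                 tolerance = 1e-9)
    expect_equal(st@suvLate[vNon[1], vNon[2], vNon[3]], 0.67,
                 tolerance = 1e-9)
})

test_that("truth masks partition the prostate and all values are finite and
           non-negative", {
    st <- simulateStudy(geometry = tinyGeom(), noiseScale = 0.4, seed = 3L)
    expect_equal(sum(st@mask == 1L) + sum(st@mask == 2L),
                 sum(st@mask > 0L))
    expect_gt(sum(st@mask == 2L), 0)
    expect_true(all(is.finite(st@petDynamic)) && all(st@petDynamic >= 0))
    expect_true(all(is.finite(st@ctpDynamic)) && all(st@ctpDynamic >= 0))
    vox <- which(st@mask > 0L)
    for (nm in mapNames())
        expect_true(all(is.finite(st@truthMaps[[nm]][vox])))
})

test_that("default geometry pools about the reported voxel count over 15
           patients", {
    mask <- DILmapper:::buildMask(phantomGeometry())
    pooled <- 15 * sum(mask > 0L)
    expect_lt(abs(pooled - 49254) / 49254, 0.20)
    # and the DIL occupies roughly the requested fraction
    frac <- sum(mask == 2L) / sum(mask > 0L)
    expect_gt(frac, 0.06)
    expect_lt(frac, 0.20)
})

test_that("frame noise is mean-zero: averaged replicates approach the
           noiseless study", {
    g <- phantomGeometry(dim = c(2L, 2L, 2L), dilFrac = 0.2, pad = 0L)
    clean <- simulateStudy(dilTissueSpec(0), nondilTissueSpec(0), g,
                           noiseScale = 0, seed = 1L)
    noisyMean <- function(M) {
        acc <- 0
        for (r in seq_len(M))
            acc <- acc + simulateStudy(dilTissueSpec(0), nondilTissueSpec(0),
                                       g, noiseScale = 0.3,
                                       seed = 100L + r)@petDynamic
        max(abs(acc / M - clean@petDynamic))
    }
    d8 <- noisyMean(8); d64 <- noisyMean(64)
    expect_lt(d64, d8)
    expect_lt(d64, 3 * d8 / sqrt(64 / 8))   # ~ 1/sqrt(M) shrinkage, loose
})

test_that("cohort generation jitters patients reproducibly", {
    g <- tinyGeom()
    co <- makeCohort(3L, geometry = g, noiseScale = 0, seeds = 1:3,
                     patientJitter = 0.15)
    expect_length(co, 3L)
    expect_false(identical(co[[1]]@truthMaps$K1, co[[2]]@truthMaps$K1))
    co2 <- makeCohort(3L, geometry = g, noiseScale = 0, seeds = 1:3,
                      patientJitter = 0.15)
    expect_identical(co[[2]]@petDynamic, co2[[2]]@petDynamic)
    # zero jitter: all patients share the reference parameters
    flat <- makeCohort(2L, geometry = g, noiseScale = 0, seeds = 1:2,
                       patientJitter = 0,
                       dilSpec = dilTissueSpec(0),
                       nondilSpec = nondilTissueSpec(0))
    expect_identical(flat[[1]]@truthMaps$K1, flat[[2]]@truthMaps$K1)
    expect_error(makeCohort(3L, seeds = 1:2), "fewer seeds")
    expect_error(makeCohort(1L), "at least 2")
})

test_that("parameter-space cohorts honour contrast restriction and seeds", {
    tab <- simulateVoxelCohort(nPatients = 6L, voxelsPerPatient = 200L,
                               contrast = c("Ki", "k4"), seed = 9L)
    tab2 <- simulateVoxelCohort(nPatients = 6L, voxelsPerPatient = 200L,
                                contrast = c("Ki", "k4"), seed = 9L)
    expect_identical(tab, tab2)
    validateVoxelTable(tab)
    med <- function(col, lab) median(tab[[col]][tab$label == lab])
    # contrast columns separate the classes; k2 (restricted) does not
    expect_gt(med("Ki", 1) / med("Ki", 0), 1.2)
    expect_lt(med("k4", 1) / med("k4", 0), 0.8)
    expect_lt(abs(log(med("k2", 1) / med("k2", 0))), 0.15)
    expect_error(simulateVoxelCohort(contrast = "nope"), "unknown map")
})

test_that("full-contrast parameter cohorts pool about the reported voxel
           count", {
    tab <- simulateVoxelCohort(seed = 2L)
    expect_lt(abs(nrow(tab) - 49254) / 49254, 0.20)
    expect_equal(length(unique(tab$patient)), 15L)
})
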