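# F2TC impulse response, forward model and derived parameters.

test_that("F2TC impulse response has the piecewise vascular/exchange form", {
    p <- dilReferenceF2TC(t0 = 4)
    expect_equal(f2tcIRF(p, c(0, 2, 3.9)), c(0, 0, 0))
    expect_equal(f2tcIRF(p, c(4, 8, 4 + p@W - 1e-6)), rep(p@F, 3))
    # continuous from the exchange side: H(t0+W) = K1
    expect_equal(f2tcIRF(p, 4 + p@W), p@K1)
    h <- f2tcIRF(p, seq(0, 1330, by = 0.5))
    expect_true(all(h >= 0 & h <= p@F + 1e-12))
})

test_that("k3 = 0 collapses the exchange response to K1 exp(-k2 t)", {
    p <- F2TCParams(F = 0.5, W = 10, K1 = 0.3, k2 = 0.4, k3 = 0, k4 = 0.1,
                    t0 = 0)
    tm <- c(0.5, 2, 10)
    expect_equal(f2tcIRF(p, 10 + 60 * tm), 0.3 * exp(-0.4 * tm),
                 tolerance = 1e-12)
})

test_that("repeated eigenvalue root uses the analytic limit", {
    # k3 = 0, k2 = k4 makes the discriminant exactly zero
    p <- F2TCParams(F = 0.5, W = 5, K1 = 0.3, k2 = 0.2, k3 = 0, k4 = 0.2,
                    t0 = 0)
    tm <- c(0.1, 1, 5)
    expect_equal(f2tcIRF(p, 5 + 60 * tm), 0.3 * exp(-0.2 * tm),
                 tolerance = 1e-9)
    # and a perturbed neighbour agrees closely (continuity in parameters)
    p2 <- F2TCParams(F = 0.5, W = 5, K1 = 0.3, k2 = 0.2 + 1e-7, k3 = 0,
                     k4 = 0.2, t0 = 0)
    expect_equal(f2tcIRF(p2, 5 + 60 * tm), f2tcIRF(p, 5 + 60 * tm),
                 tolerance = 1e-5)
})

test_that("exchange response matches stiff ODE integration of the
           compartment system for random parameter draws", {
    skip_if_not_installed("deSolve")
    for (p in randomF2TC(100, seed = 7)) {
        tm <- c(0.5, 2, 10, 21)
        analytic <- f2tcIRF(p, p@t0 + p@W + 60 * tm)
        ode <- vapply(tm, function(x) odeIRF(p@K1, p@k2, p@k3, p@k4, x),
                      numeric(1))
        expect_lt(max(abs(analytic - ode) / pmax(abs(ode), 1e-12)), 1e-4)
    }
})

test_that("forward model is linear in the AIF and zero for a zero AIF", {
    sch <- petFrameSchedule()
    p <- dilReferenceF2TC()
    tg <- seq(0, 1330, by = 0.5)
    zero <- TimeActivityCurve(tg, numeric(length(tg)))
    expect_true(all(curveValues(f2tcForward(p, zero, sch)) == 0))
    a1 <- makeAIF(petDefaultAIF(), tg)
    scaled <- TimeActivityCurve(tg, 2.5 * curveValues(a1))
    expect_equal(curveValues(f2tcForward(p, scaled, sch)),
                 2.5 * curveValues(f2tcForward(p, a1, sch)),
                 tolerance = 1e-12)
})

test_that("forward model matches the refined-grid convolution oracle", {
    sch <- petFrameSchedule()
    aif <- petDefaultAIF()
    for (p in c(list(dilReferenceF2TC(t0 = 3), nondilReferenceF2TC()),
                randomF2TC(3, seed = 11))) {
        pkg <- curveValues(f2tcForward(p, aif, sch))
        oracle <- bruteForwardTAC(function(t) f2tcIRF(p, t), aif, sch,
                                  dt = 0.01)
        expect_lt(max(abs(pkg - oracle)) / max(oracle), 1e-4)
    }
})

test_that("forward model rejects a schedule past the AIF support", {
    tg <- seq(0, 600, by = 0.5)
    aif <- makeAIF(petDefaultAIF(), tg)
    expect_error(f2tcForward(dilReferenceF2TC(), aif, petFrameSchedule()),
                 "support")
})

test_that("Ki identity closes on the reference sets and handles edge cases", {
    expect_equal(kiOf(dilReferenceF2TC()), 0.055, tolerance = 1e-12)
    expect_equal(kiOf(nondilReferenceF2TC()), 0.036, tolerance = 1e-12)
    p <- F2TCParams(F = 0.5, W = 5, K1 = 0.3, k2 = 0.4, k3 = 0, k4 = 0.1)
    expect_equal(kiOf(p), 0)
    expect_error(kiOf(F2TCParams(F = 0.5, W = 5, K1 = 0.3, k2 = 0, k3 = 0,
                                 k4 = 0.1)), "undefined")
    # Ki <= K1 always
    for (q in randomF2TC(20, seed = 3)) expect_lte(kiOf(q), q@K1)
})

test_that("Ki equals the Patlak asymptotic slope of a k4 = 0 simulation", {
    set.seed(5)
    for (r in 1:3) {
        p <- F2TCParams(F = 1, W = 0, K1 = runif(1, 0.1, 0.4),
                        k2 = runif(1, 0.1, 0.6), k3 = runif(1, 0.02, 0.2),
                        k4 = 0, t0 = 0)
        # long late frames so the system reaches its Patlak asymptote
        ends <- c(seq(60, 600, by = 60), seq(900, 14400, by = 300))
        sch <- FrameSchedule(c(0, ends[-length(ends)]), ends)
        aif <- petDefaultAIF()
        tac <- curveValues(f2tcForward(p, aif, sch, dt = 1))
        tg <- seq(0, max(ends), by = 1)
        A <- curveValues(makeAIF(aif, tg))
        cumA <- cumsum(c(0, (A[-1] + A[-length(A)]) / 2)) / 60  # kBq/mL*min
        mid <- frameMid(sch)
        Cp <- approx(tg, A, mid)$y
        x <- approx(tg, cumA, mid)$y / Cp
        y <- tac / Cp
        late <- x > 0.8 * max(x)
        slope <- coef(lm(y[late] ~ x[late]))[2]
        expect_equal(unname(slope), kiOf(p), tolerance = 0.01)
    }
})

test_that("DV identity closes on the reference sets and equals the IRF area", {
    expect_equal(dvOf(dilReferenceF2TC()), 2.29, tolerance = 1e-12)
    expect_equal(dvOf(nondilReferenceF2TC()), 1.17, tolerance = 1e-12)
    p <- F2TCParams(F = 0.5, W = 5, K1 = 0.3, k2 = 0.4, k3 = 0, k4 = 0.1)
    expect_equal(dvOf(p), 0.3 / 0.4)
    expect_warning(res <- dvOf(F2TCParams(F = 0.5, W = 5, K1 = 0.3, k2 = 0.4,
                                          k3 = 0.1, k4 = 0)), "undefined")
    expect_true(is.na(res))
    # quadrature: integral of the post-window response (minutes) equals DV
    for (q in randomF2TC(10, seed = 9)) {
        area <- integrate(function(tm) f2tcIRF(q, q@t0 + q@W + 60 * tm),
                          0, Inf, rel.tol = 1e-9)$value
        expect_equal(area, dvOf(q), tolerance = 0.005)
    }
})

test_that("SUV arithmetic follows dose-per-weight normalization", {
    expect_equal(suv(325 / 88.8, 325, 88.8), 1)
    expect_equal(suv(0, 325, 88.8), 0)
    expect_equal(suv(5, 325, 88.8), 5 * 88.8 / 325)
    expect_error(suv(1, 0, 70), "dose")
    expect_error(suv(1, 300, 0), "weight")
})

test_that("SUV_Early averages exactly the frames from 10 min onward", {
    sch <- petFrameSchedule()
    cd <- cohortDefaults()
    const <- TimeActivityCurve(frameMid(sch), rep(3, 28))
    expect_equal(suvEarly(const, sch, cd$dose, cd$weight),
                 suv(3, cd$dose, cd$weight))
    v <- numeric(28); v[25:28] <- c(2, 4, 6, 8)
    tac <- TimeActivityCurve(frameMid(sch), v)
    expect_equal(suvEarly(tac, sch, cd$dose, cd$weight),
                 suv(5, cd$dose, cd$weight))
    # frame 24 starts at 550 s < 10 min: it must not contribute
    v2 <- v; v2[24] <- 100
    tac2 <- TimeActivityCurve(frameMid(sch), v2)
    expect_equal(suvEarly(tac2, sch, cd$dose, cd$weight),
                 suv(5, cd$dose, cd$weight))
    expect_error(suvEarly(TimeActivityCurve(c(5, 15), c(1, 1)),
                          FrameSchedule(c(0, 10), c(10, 20)), 325, 88.8),
                 "4 frames")
})
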