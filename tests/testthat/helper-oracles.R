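# Independent reference implementations used as oracles. These deliberately
# avoid the package's convolution engine: brute-force quadrature, direct ODE
# integration, exhaustive enumeration.

# brute-force convolution of a closed-form AIF with a pointwise IRF on a
# refined uniform grid (trapezoid weights via FFT convolution), then
# trapezoidal frame averaging -- algorithmically unrelated to the package's
# recursive convolution engine
bruteForwardTAC <- function(irfFun, aifModel, schedule, dt = 0.05,
                            scale = 1 / 60) {
    tEnd <- max(frameEnd(schedule))
    tg <- seq(0, tEnd, by = dt)
    A <- curveValues(makeAIF(aifModel, tg))
    n <- length(tg)
    # half-jump convention at the IRF's discontinuities keeps the trapezoid
    # rule second-order accurate
    H <- (irfFun(tg - 1e-9) + irfFun(tg + 1e-9)) / 2
    full <- stats::convolve(A, rev(H), type = "open")[seq_len(n)] * dt
    # rectangle -> trapezoid: halve the two endpoint terms of each sum
    C <- (full - 0.5 * dt * (A[1L] * H + A * H[1L])) * scale
    C[1L] <- 0
    vapply(seq_len(nFrames(schedule)), function(j) {
        idx <- which(tg >= frameStart(schedule)[j] - 1e-9 &
                     tg <= frameEnd(schedule)[j] + 1e-9)
        y <- C[idx]
        sum((y[-1] + y[-length(y)]) / 2) * dt /
            (frameEnd(schedule)[j] - frameStart(schedule)[j])
    }, numeric(1))
}

# two-tissue compartment impulse response by stiff ODE integration:
# bolus K1 into the free compartment at t' = 0, h = C1 + C2
odeIRF <- function(K1, k2, k3, k4, tMin) {
    stopifnot(requireNamespace("deSolve", quietly = TRUE))
    rhs <- function(t, y, parms)
        list(c(-(k2 + k3) * y[1] + k4 * y[2], k3 * y[1] - k4 * y[2]))
    out <- deSolve::lsoda(c(K1, 0), c(0, tMin), rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
    rowSums(out[-1, 2:3, drop = FALSE])
}

# exhaustive 2^n sign-permutation two-sided p of the signed-rank statistic
exhaustiveSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    pLow <- mean(Ws <= W + 1e-9)
    pHigh <- mean(Ws >= W - 1e-9)
    min(1, 2 * min(pLow, pHigh))
}

# Newton-Raphson logistic regression on a raw design matrix (with intercept)
newtonLogistic <- function(X, y, tol = 1e-12, maxit = 200) {
    X <- cbind(1, X)
    b <- rep(0, ncol(X))
    for (i in seq_len(maxit)) {
        eta <- drop(X %*% b)
        p <- 1 / (1 + exp(-eta))
        g <- drop(t(X) %*% (y - p))
        Wd <- p * (1 - p)
        H <- t(X) %*% (X * Wd)
        step <- solve(H, g)
        b <- b + step
        if (max(abs(step)) < tol) break
    }
    b
}

# brute-force AUC over all positive/negative pairs, ties one half
bruteAUC <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    s <- 0
    for (p in pos) for (q in neg)
        s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    s / (length(pos) * length(neg))
}

# random valid F2TC parameter vectors, bounded away from degeneracy
randomF2TC <- function(n, seed = 1) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
        Fv <- runif(1, 0.2, 1.5)
        # W and t0 on a 0.01 s lattice so the refined-grid oracle's samples
        # land exactly on the response's jump points
        F2TCParams(F = Fv, W = round(runif(1, 2, 20), 2),
                   K1 = Fv * runif(1, 0.2, 0.9),
                   k2 = runif(1, 0.05, 1), k3 = runif(1, 0.01, 0.5),
                   k4 = runif(1, 0.02, 0.5), t0 = round(runif(1, 0, 10), 2))
    })
}

randomATH <- function(n, seed = 1) {
    set.seed(seed)
    lapply(seq_len(n), function(i)
        ATHParams(BF = runif(1, 20, 120), Tc = round(runif(1, 3, 15), 2),
                  E = runif(1, 0.1, 0.6), Ve = runif(1, 5, 30),
                  T0 = round(runif(1, 0, 8), 2)))
}

tinyGeom <- function(dim = c(6L, 6L, 2L), pad = 1L)
    phantomGeometry(dim = dim, spacing = c(2, 2, 3.27), dilFrac = 0.15,
                    pad = pad)

relErr <- function(x, ref) abs(x - ref) / abs(ref)
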