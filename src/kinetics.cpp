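#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared machinery for the two frame-averaged convolution models.
//
// Both tissue models are a convolution of an arterial input curve A(t),
// supplied sampled on a uniform fine grid t_i = i * dt starting at 0, with a
// piecewise impulse response made of (a) a rectangular vascular window and
// (b) shifted decaying exponentials.  Each piece convolves in O(n):
//   * rectangle  -> difference of the cumulative integral of A,
//   * exponential-> first-order recursion exact for piecewise-linear A.
// Frame averages come from the cumulative integral of the tissue curve.

namespace {

// trapezoidal cumulative integral of y on a uniform grid (cum[0] = 0)
std::vector<double> cumtrap(const NumericVector& y, double dt) {
    const int n = y.size();
    std::vector<double> c(n, 0.0);
    for (int i = 1; i < n; ++i)
        c[i] = c[i - 1] + 0.5 * dt * (y[i] + y[i - 1]);
    return c;
}

// linear interpolation of v (on grid i*dt) at time t; 0 before grid start,
// clamped to the last value past the end
double interp_at(const std::vector<double>& v, double dt, double t) {
    if (t <= 0.0) return 0.0;
    const double x = t / dt;
    const int i = (int)std::floor(x);
    const int n = (int)v.size();
    if (i >= n - 1) return v[n - 1];
    const double f = x - i;
    return v[i] * (1.0 - f) + v[i + 1] * f;
}

// y(t_i) = int_0^{t_i} A(u) exp(-rate * (t_i - u)) du, rate in 1/s
std::vector<double> expconv(const NumericVector& A, double dt, double rate) {
    const int n = A.size();
    std::vector<double> y(n, 0.0);
    const double d = std::exp(-rate * dt);
    for (int i = 1; i < n; ++i)
        y[i] = y[i - 1] * d + 0.5 * dt * (A[i] + A[i - 1] * d);
    return y;
}

// frame means of the tissue curve C (on grid dt) over [start_j, end_j]
NumericVector frame_means(const std::vector<double>& C, double dt,
                          const NumericVector& fstart,
                          const NumericVector& fend) {
    std::vector<double> cumC(C.size(), 0.0);
    for (size_t i = 1; i < C.size(); ++i)
        cumC[i] = cumC[i - 1] + 0.5 * dt * (C[i] + C[i - 1]);
    const int nf = fstart.size();
    NumericVector out(nf);
    for (int j = 0; j < nf; ++j) {
        const double a = interp_at(cumC, dt, fstart[j]);
        const double b = interp_at(cumC, dt, fend[j]);
        out[j] = (b - a) / (fend[j] - fstart[j]);
    }
    return out;
}

} // namespace

// Tissue curve of the flow-modified two-tissue-compartment model on the fine
// grid, frame-averaged.  Parameter vector: F, W_s, K1, k2, k3, k4, t0_s with
// F, K1 in mL/min/g, k's in 1/min, W and t0 in seconds.  A is the arterial
// curve on the uniform grid (dt seconds); result has the same frame order as
// fstart/fend.
// [[Rcpp::export(name = ".f2tc_frame_conv")]]
NumericVector f2tc_frame_conv(NumericVector par, NumericVector A, double dt,
                              NumericVector fstart, NumericVector fend) {
    const double F = par[0], W = par[1], K1 = par[2];
    const double k2 = par[3], k3 = par[4], k4 = par[5], t0 = par[6];
    const int n = A.size();

    const std::vector<double> cumA = cumtrap(A, dt);

    const double s = k2 + k3 + k4;
    double disc = s * s - 4.0 * k2 * k4;
    if (disc < 1e-12) disc = 1e-12;   // near-repeated root: clamp
    const double root = std::sqrt(disc);
    const double alpha = 0.5 * (s - root);
    const double beta  = 0.5 * (s + root);
    const double ca = K1 * (k3 + k4 - alpha) / root;  // coefficient of e^{-alpha t'}
    const double cb = K1 * (beta - k3 - k4) / root;

    // exponential convolutions with unshifted A (rates converted to 1/s)
    const std::vector<double> za = expconv(A, dt, alpha / 60.0);
    const std::vector<double> zb = expconv(A, dt, beta / 60.0);

    std::vector<double> C(n, 0.0);
    const double shift = t0 + W;
    for (int i = 0; i < n; ++i) {
        const double t = i * dt;
        // vascular window: F * integral of A over [t - t0 - W, t - t0],
        // with the per-minute flow converted to per-second
        const double vasc = F / 60.0 *
            (interp_at(cumA, dt, t - t0) - interp_at(cumA, dt, t - shift));
        const double exch = (ca * interp_at(za, dt, t - shift) +
                             cb * interp_at(zb, dt, t - shift)) / 60.0;
        C[i] = vasc + exch;
    }
    return frame_means(C, dt, fstart, fend);
}

// Adiabatic tissue-homogeneity (Johnson-Wilson) tissue curve, frame-averaged.
// Parameter vector: BF (mL/min/100g), Tc_s, E, Ve (mL/100g), T0_s.
// Tissue curve = BF/6000 * [ rect(T0, Tc) + E exp(-E BF (t-T0-Tc)/(60 Ve)) ] (*) A
// (BF/6000 = flow per gram per second; 1 g/mL density gives HU enhancement)
// [[Rcpp::export(name = ".ath_frame_conv")]]
NumericVector ath_frame_conv(NumericVector par, NumericVector A, double dt,
                             NumericVector fstart, NumericVector fend) {
    const double BF = par[0], Tc = par[1], E = par[2];
    const double Ve = par[3], T0 = par[4];
    const int n = A.size();

    const std::vector<double> cumA = cumtrap(A, dt);
    const double kb = (Ve > 0.0) ? E * BF / (60.0 * Ve) : 0.0;  // 1/s
    const std::vector<double> z = expconv(A, dt, kb);

    std::vector<double> C(n, 0.0);
    const double shift = T0 + Tc;
    for (int i = 0; i < n; ++i) {
        const double t = i * dt;
        const double vasc = interp_at(cumA, dt, t - T0) -
                            interp_at(cumA, dt, t - shift);
        const double leak = E * interp_at(z, dt, t - shift);
        C[i] = BF / 6000.0 * (vasc + leak);
    }
    return frame_means(C, dt, fstart, fend);
}
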