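# Reference kinetic parameter sets for the two tissue classes.
#
# The generating values are anchored to the cohort's published per-class
# medians: K1, k4, Ki and DV (PET) and BF, MTT, PS (CTP). The free rates k2
# and k3 are the unique solution of the two identities
#   Ki = K1 k3 / (k2 + k3)        DV = (K1/k2)(1 + k3/k4),
# and the ATH extraction fraction inverts the Crone-Renkin relation
#   E = 1 - exp(-PS/BF).
# Solving at run time (rather than storing rounded numbers) makes kiOf/dvOf/
# psOf close on the medians exactly.

solveK2K3 <- function(K1, k4, Ki, DV) {
    r <- Ki / K1                     # = k3 / (k2 + k3)
    k2 <- K1 / (DV - K1 * r / ((1 - r) * k4))
    k3 <- k2 * r / (1 - r)
    c(k2 = k2, k3 = k3)
}

#' Reference F2TC parameter set of DIL tissue
#'
#' Anchored to the DIL medians K1 = 0.236 mL/min/g, k4 = 0.085 1/min,
#' Ki = 0.055 mL/min/g, DV = 2.29 mL/g; vascular phase F = 0.5658 mL/min/g
#' and W = 8.94 s taken from the DIL perfusion medians (1 g/mL density).
#'
#' @param t0 tissue bolus delay in seconds (default 0; the arterial model
#'   carries its own arrival delay).
#' @return An [F2TCParams-class].
#' @examples
#' kiOf(dilReferenceF2TC())   # 0.055 by construction
#' @export
dilReferenceF2TC <- function(t0 = 0) {
    k <- solveK2K3(K1 = 0.236, k4 = 0.085, Ki = 0.055, DV = 2.29)
    F2TCParams(F = 56.58 / 100, W = 8.94, K1 = 0.236,
               k2 = k[["k2"]], k3 = k[["k3"]], k4 = 0.085, t0 = t0)
}

#' Reference F2TC parameter set of non-DIL prostate tissue
#'
#' Anchored to the non-DIL medians K1 = 0.187 mL/min/g, k4 = 0.130 1/min,
#' Ki = 0.036 mL/min/g, DV = 1.17 mL/g; F = 0.4643 mL/min/g, W = 8.07 s.
#'
#' @inheritParams dilReferenceF2TC
#' @return An [F2TCParams-class].
#' @export
nondilReferenceF2TC <- function(t0 = 0) {
    k <- solveK2K3(K1 = 0.187, k4 = 0.130, Ki = 0.036, DV = 1.17)
    F2TCParams(F = 46.43 / 100, W = 8.07, K1 = 0.187,
               k2 = k[["k2"]], k3 = k[["k3"]], k4 = 0.130, t0 = t0)
}

#' Reference ATH parameter set of DIL tissue
#'
#' Anchored to the DIL perfusion medians BF = 56.58 mL/min/100g,
#' MTT = 8.94 s, PS = 24.39 mL/min/100g (so E = 1 - exp(-PS/BF)); the
#' interstitial volume Ve = 15 mL/100g is a representative soft-tissue value.
#'
#' @param T0 contrast arrival delay in seconds (default 2).
#' @return An [ATHParams-class].
#' @export
dilReferenceATH <- function(T0 = 2) {
    ATHParams(BF = 56.58, Tc = 8.94, E = 1 - exp(-24.39 / 56.58),
              Ve = 15, T0 = T0)
}

#' Reference ATH parameter set of non-DIL prostate tissue
#'
#' Anchored to the non-DIL perfusion medians BF = 46.43 mL/min/100g,
#' MTT = 8.07 s, PS = 19.44 mL/min/100g; Ve = 15 mL/100g.
#'
#' @inheritParams dilReferenceATH
#' @return An [ATHParams-class].
#' @export
nondilReferenceATH <- function(T0 = 2) {
    ATHParams(BF = 46.43, Tc = 8.07, E = 1 - exp(-19.44 / 46.43),
              Ve = 15, T0 = T0)
}

#' Cohort defaults for dose and body weight
#'
#' Injected activity 325 MBq and mean body weight 88.8 kg.
#' @return Named list with `dose` (MBq) and `weight` (kg).
#' @export
cohortDefaults <- function() list(dose = 325, weight = 88.8)
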