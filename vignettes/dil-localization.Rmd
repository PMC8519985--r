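---
title: "Kinetic-model localization of dominant intraprostatic lesions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-model localization of dominant intraprostatic lesions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DILmapper)
```

## The problem

Prostate-specific membrane antigen (PSMA) PET tracers accumulate strongly
in prostate cancer, and the *kinetics* of that accumulation over the first
twenty minutes after injection carry information that a single static image
does not: delivery (flow), exchange with the free tissue compartment, and
binding/dissociation at the PSMA receptor. DILmapper implements a complete
desk-scale replica of a short-scan kinetic analysis: simulate dynamic
PET/CT-perfusion studies of a two-class prostate (dominant lesion vs benign
gland), estimate voxel-wise kinetic parameters, and ask which parameters —
alone or in combination — best classify lesion voxels, validated patient-wise.

Because clinical images of this kind are not publicly distributable, the
package treats the *digital phantom generator* as a first-class module: its
defaults encode the study conditions (acquisition schedules, class-median
kinetic contrast, cohort size, voxel counts), and every downstream module is
tested against data it produces.

## Models

### Flow-modified two-tissue compartment (F2TC)

A voxel's impulse response is a rectangular vascular window followed by the
reversible two-tissue-compartment response,

$$H(t)=\begin{cases}
0 & t<t_0\\
F & t_0\le t<t_0+W\\
K_1\,\dfrac{(k_3+k_4-\alpha)e^{-\alpha t'}+(\beta-k_3-k_4)e^{-\beta t'}}{\beta-\alpha} & t'=t-t_0-W\ge 0,
\end{cases}$$

with eigenvalues
$\alpha,\beta=\tfrac12\big[(k_2+k_3+k_4)\mp\sqrt{(k_2+k_3+k_4)^2-4k_2k_4}\big]$.
$H$ is continuous from the exchange side ($H(t_0+W)=K_1$) and bounded by
$F$ because the single-pass extraction $K_1/F$ cannot exceed one — the
fitter enforces this by estimating the extraction on $[0,1]$ rather than
$K_1$ directly. The tissue curve is the convolution of the arterial input
with $H$, averaged over each acquisition frame (that is what a PET frame
reports). Derived parameters:

* $K_i = K_1 k_3/(k_2+k_3)$ (mL/min/g), the net uptake rate constant —
  equal to the asymptotic Patlak slope when $k_4=0$ (a property test checks
  this against a Patlak regression on simulated late frames);
* $\mathrm{DV} = (K_1/k_2)(1+k_3/k_4)$ (mL/g), the distribution volume of
  the exchangeable compartments. It equals the time-integral of the
  post-window impulse response (checked by quadrature), and deliberately
  excludes the vascular window's area $F\cdot W$. DV is undefined at
  $k_2=0$ or $k_4=0$; `dvOf()` returns `NA` with a warning rather than a
  silent number. We report DV in mL/g, the scale on which the class medians
  are quoted.

Assumptions worth stating: a single arterial curve serves as input (no
whole-blood/plasma distinction, no metabolite correction); activities are
decay-corrected to injection; tissue density is 1 g/mL, making per-g and
per-mL interchangeable.

### Adiabatic tissue homogeneity (CT perfusion)

The contrast residue function is plug-flow during the capillary transit
and mono-exponential interstitial washout afterwards:
$R(t)=1$ on $[T_0, T_0+T_c)$, then $E\,e^{-E\,\mathrm{BF}\,(t-T_0-T_c)/(60 V_e)}$.
Tissue enhancement is $\mathrm{BF}\cdot(\mathrm{AIF}\ast R)$ (per gram,
unit density). Derived: $\mathrm{BV}=\mathrm{BF}\cdot\mathrm{MTT}/60$,
$\mathrm{MTT}=T_c$, $\mathrm{PS}=-\mathrm{BF}\ln(1-E)$.

Two design decisions here were genuinely open. First, commercial CTP
software does not document whether MTT means the vascular transit time or
BV/BF of a broader space; we define MTT as the capillary transit time
$T_c$, which makes BF, MTT and PS independently settable so that all three
class medians can be represented simultaneously. Second, the published DIL
medians violate the central-volume identity ($\mathrm{BV}\neq
\mathrm{BF}\cdot\mathrm{MTT}/60$ by about 6%), so the generator cannot
match the BV median while honouring the identity; we honour the identity
(BV is always derived, never independently fitted) and accept that the BV
median is approximate. Hounsfield-to-concentration conversion is omitted —
curves are already concentration-like — and phantoms are motion-free.

## Reference parameter sets

Class-reference kinetics are anchored to the cohort's per-class medians:
K1 = 0.236 / 0.187 mL/min/g, k4 = 0.085 / 0.130 min⁻¹, Ki = 0.055 / 0.036
mL/min/g, DV = 2.29 / 1.17 mL/g (DIL / non-DIL), BF = 56.58 / 46.43
mL/min/100g, MTT = 8.94 / 8.07 s, PS = 24.39 / 19.44 mL/min/100g,
SUV_Early 2.53 / 1.78 and SUV_Late 1.55 / 0.67 g/mL. The free rates
$k_2,k_3$ are the unique solution of the Ki and DV identities given K1 and
k4 (solved in closed form at run time, so `kiOf()`/`dvOf()` close on the
medians exactly), and the ATH extraction fraction inverts Crone–Renkin,
$E=1-e^{-\mathrm{PS/BF}}$. The PET vascular phase borrows the perfusion
medians ($F=\mathrm{BF}/100$ per gram, $W=\mathrm{MTT}$). The interstitial
volume $V_e = 15$ mL/100g is a representative soft-tissue value (it is not
printed anywhere); tissue delays default to 0 s (PET) and 2 s (CTP) since
the arterial models carry their own arrival delays.

## The phantom generator

`simulateStudy()` builds one patient: a padded 20×20×8-voxel prostate
block at 2×2×3.27 mm (the slice thickness of the dynamic scan) with an
off-centre ellipsoidal DIL of ~12% of prostate voxels — a 15-patient
cohort then pools ≈48,000 prostate voxels, matching the ~49,254 analyzed
voxels of the study conditions. Acquisition follows the published
schedules exactly: 28 PET frames (11×10 s, 5×20 s, 4×40 s, 4×60 s,
4×180 s; 0–1330 s) and two-phase CTP sampling (2.8 s intervals for the
first minute, 15 s for the next two).

Arterial inputs are closed-form: a tri-exponential PET bolus (linear rise
times exponential plus two washout terms, continuous at arrival, peak ≈
60 s post-injection) and a gamma-variate contrast bolus with a delayed,
scaled recirculation bump. The published analysis used image-derived
curves whose functional form is not available; these are the standard
parametric stand-ins, and every estimator consumes the AIF generically (a
sampled curve works as well as a model object).

Per-voxel ground truth is drawn log-normally around the class reference
(`voxelJitter`, default sdlog 0.15) and per-patient log-normal jitter
(default sdlog 0.1) shifts both classes of a patient together, preserving
within-patient contrast — the structure a paired signed-rank analysis
relies on. Frame noise is mean-zero Gaussian with SD
$\sigma\sqrt{\text{value}/\Delta t}$, clamped at zero: the standard
frame-weighted proxy for PET count statistics that keeps the
duration-proportional fitting weights principled. Poisson emission
statistics, partial-volume effects, spillover, scanner resolution,
reconstruction and inter-modality registration are *not* emulated —
passing tests demonstrate correct estimation and selection machinery under
this noise model, not clinical performance on real images. The defaults
(noiseScale 0.2, the jitters above) were chosen once as plausible for
voxel-level prostate PET/CTP variability.

`simulateVoxelCohort()` samples the 13-column voxel table directly in
parameter space, with the same jitter structure, optionally restricting
class contrast to named columns. This exists because contrast confined to
exactly {Ki, k4} cannot be produced through the physical forward model —
perturbing $k_3,k_4$ necessarily moves DV and the SUV maps too — yet the
selection experiments need such cohorts. Its per-column draws are
independent, which ignores the physiological correlations among maps; the
imaging route (`simulateStudy()` → `buildMaps()`) retains them.

## Estimation and numerical choices

* **Convolution grid.** Forward models evaluate on a uniform internal grid
  with linear AIF interpolation and O(n) exponential-convolution
  recursions (exact for piecewise-linear inputs), implemented in C++. The
  grid is 0.5 s for PET — two orders below the shortest 10 s frame — and
  0.1 s for CTP, applying the same "well below the shortest frame"
  rationale to its 2.8 s sampling; at 0.5 s the sharper contrast bolus
  leaves ~10⁻³ relative discretization error, at 0.1 s it is under the
  10⁻⁴ oracle tolerance.
* **Near-repeated eigenvalues.** The scalar `f2tcIRF()` switches to the
  analytic limit $K_1 e^{-\alpha t'}(1+(k_3+k_4-\alpha)t')$ when the
  discriminant vanishes; the convolution engine clamps the discriminant at
  10⁻¹² (relative effect far below grid error).
* **Fitting.** Weighted least squares with weights proportional to frame
  duration (matching the generator's variance model), bounded
  Levenberg–Marquardt (`minpack.lm`), restarted from a fixed physiological
  midpoint plus seeded Latin-hypercube points (5 starts by default; the
  seed is an explicit option). Bounds: F, K1 ∈ [0,3] mL/min/g; k2, k3, k4
  ∈ [0,3] min⁻¹; W ∈ [0,30] s; t0 ∈ [0,60] s; BF ∈ [0,300], Tc ∈ [0,30] s,
  E ∈ [0,0.95], Ve ∈ [1,60], T0 ∈ [0,20] s. All-zero curves short-circuit
  to a flagged degenerate result; fits that never converge are flagged,
  never silently returned.
* **Smoothing.** The 3×3 in-slice mean filter precedes PET voxel fits;
  at image edges the kernel shrinks to the available in-slice neighbours
  (the alternative — zero padding — would bleed background into edge
  voxels). CTP curves are not smoothed (the clinical CTP chain applies its
  own vendor processing).
* **Wilcoxon signed-rank.** Implemented in-package: zeros discarded,
  midranks for ties, exact two-sided p by dynamic programming over the
  doubled-rank permutation distribution for n ≤ 25 (valid under ties,
  where the standard implementation abandons exactness), normal
  approximation with tie and continuity correction above. The paired unit
  is the per-patient ROI median — the only construction consistent with a
  signed-rank pairing across 15 patients — and Bonferroni uses m = 13.
* **Logistic regression and elimination.** Voxels pool across patients
  (within-patient correlation ignored — a stated limitation mirrored from
  the voxel-wise design); features are z-scored internally; the fit is
  binomial IRLS via `glm`. Complete separation triggers a lightly
  L2-penalized Newton fallback (per-observation ridge 0.01, intercept
  unpenalized), flagged in the result with Wald p-values withheld.
  Backward elimination removes the largest Wald p while any exceeds 0.05
  and stops at one feature; with two candidates and pure noise in one, the
  noise column survives at roughly the nominal 5% type-I rate — the tests
  assert that behaviour rather than a chance-perfect 20/20.
* **Cross-validation.** Feature selection is performed once on the full
  cohort and coefficients are refit per fold (the literal reading of
  validating *the selected model*); per-fold re-selection is available via
  `opts$reselect`. Folds with a single-class held-out patient have
  undefined AUC and are excluded from the AUC aggregate only. Both SD and
  SE across folds are reported. Dice compares the thresholded (default
  0.5) predicted DIL voxel set against the true one; an optional largest
  26-connected-component post-processing exists for map-level detection
  and is off by default.

## Problem sizes used by the tests

Map-level and pipeline tests run on reduced geometries (prostates of
6×6×2 down to 3×3×2 voxels, 3–10 patients, single-start fits) so the whole
suite completes in minutes; statistical property checks (selection
frequency, permutation null, model ranking) run on parameter-space cohorts
at the full pooled scale of ≈49,000 voxels, where the null distribution of
the mean LOPO AUC is tight. The acceptance script fits six noiseless
reference curves and is seconds-fast. These sizes are the package's own
test-design choices; all thresholds quoted above are fixed in the tests.

## Known limitations

* Phantom realism ends at the noise model: no spatial point-spread, no
  Poisson statistics, no motion or registration error, no bladder/vessel
  background structures.
* The AIF forms are parametric stand-ins for image-derived curves; AIF
  extraction itself is out of scope.
* The F2TC vascular-window form is one reasonable parameterization of a
  flow-modified model; other parameterizations of the vascular phase exist.
* Voxel-wise logistic pooling ignores within-patient correlation; the
  LOPO validation, not the pooled Wald p-values, is the honest performance
  readout.
* The published clinical endpoint values (fold-averaged AUC/ER/Dice on 15
  patients' images) are patient-data quantities; the package's tests check
  parameter recovery, oracle equivalence and directional properties, not
  those numbers.
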