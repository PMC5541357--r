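---
title: "Models and numerical methods in saskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in saskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saskit)
```

This vignette documents the models behind each analysis layer, the tunable
parameters with their defaults and units, the numerical choices made where
several implementations are defensible, and what the synthetic-data tests
do and do not demonstrate about real measurements.

## The data model

A `scattering_curve` holds a background-subtracted, radially averaged 1D
profile: a strictly increasing momentum-transfer grid `s = 4π sin θ / λ`
(internally always in Å⁻¹; nm⁻¹ converted at the boundary by the exact
factor 10), intensities on an arbitrary relative or absolute scale, and
optional strictly positive 1σ errors. Operations that are statistically
meaningless without errors (averaging, χ², the indirect transform, body
fitting) refuse curves lacking them rather than imputing — the comparison
statistics are σ-sensitive and silent imputation would miscalibrate them.
Curve arithmetic never interpolates silently: grids must match to 1e-6
relative, and regridding is an explicit, separate step.

## Curve comparison

Two tests are provided. The reduced χ² statistic
`χ²ᵣ = Σ (Iₐ−I_b)²/σ² / ν`, `ν = n − 1 − dof_extra`, is exact under
Gaussian errors but requires the errors to be right. The correlation-map
test needs none: under the null the signs of the pointwise differences
are fair coin flips, and the probability that the longest same-sign run
reaches `C` is computed exactly. A length-`n` binary string whose maximal
runs are all ≤ m is determined by its first symbol and a composition of
`n` into parts ≤ m; running the composition recurrence directly in
probability space (each term weighted by `2⁻ʲ`, with a sliding window
sum) is O(n), suffers no integer overflow, and is stable to at least
`n = 10⁴`. Exact zero differences take positive sign — a deterministic
convention that essentially never triggers on real data but makes the
statistic reproducible bit-for-bit. The paired Student t-test on
standardized differences is included for reference only. Pairwise set
comparison applies Bonferroni over the `k(k−1)/2` pairs by default.

Because the run statistic is discrete, its achievable test levels are a
finite set; calibration tests therefore compare the empirical rejection
rate against the largest achievable level ≤ 5%, not against 5% itself.

## Guinier analysis

The globular fit regresses `ln I` on `s²` with weights `(I/σ)²`
(the log-transform propagation of σ), yielding `Rg² = −3·slope`; the rod
and sheet variants transform to `ln(sI)` and `ln(s²I)` with slope factors
2 and 1, giving the cross-section and thickness radii. The approximation
carries a systematic curvature bias that grows with the window: for an
ideal sphere the Rg error is ≈0.7% at `sRg ≤ 0.8` and ≈1.9% at the
standard working cap of 1.3. Closed-form validation therefore uses deep
windows (`sRg ≤ 0.8`, rod `sRc ≤ 0.6`, sheet `sRt ≤ 0.4`), while
`autorg()` deliberately works at the conventional cap where the
statistical error of real data dominates the residual bias.

`autorg()` scans every window of ≥ 5 points whose self-consistent upper
bound satisfies `s·Rg ≤ cap` (default 1.3, configurable; the scan uses
cumulative sums so all windows cost O(1) each). Windows are scored by a
weighted geometric mean — R² (weight 0.4), fraction of the allowed range
covered (0.3), closeness of the upper bound to the cap (0.2), and a
penalty for discarding leading points (0.1) — with ties broken toward the
earliest start. The score weights are this package's definition; on noisy
data the choice mostly affects which of several near-equivalent windows is
reported, not the fitted Rg.

## Regularized indirect Fourier transform

`ift_solve()` discretizes `I(s) = 4π ∫₀^{Dmax} p(r) sinc(sr) dr` on a
uniform `r` grid (`npts` default 101, trapezoid weights) and minimizes
`χ² + α·Ω(p)` with `Ω` the squared first differences (squared second
differences by option). End constraints `p(0) = p(Dmax) = 0` are enforced
by default and releasable. The normal equations are solved by dense
factorization; `α` is internally rescaled by the ratio of the data-term
and smoothness-term diagonals so that user-facing values are comparable
across problems. Errors on `p` come from the covariance of the
regularized inverse operator.

Solution quality is summarized by six perceptual criteria in [0, 1],
averaged with equal weights into a "total estimate": DISCRP
`exp(−|χ²ᵣ−1|)`, OSCILL (inverse arc-length ratio of the normalized p to
a single-node half-sine), STABIL (insensitivity of p to ±10%
perturbations of α), SYSDEV (exact longest-run probability of the
residual signs), POSITV (positive fraction of the absolute area) and
VALCEN (fraction of |p| mass in the central 80% of [0, Dmax]). These
formulas are this package's concrete definitions of long-standing
perceptual criteria names. Automatic `α` maximizes the total on
`log₁₀ α ∈ [−8, 4]`; the surface need not be unimodal, so a 0.5-decade
grid locates the global ridge before golden-section refinement
(tolerance 0.01 decades).

### Automatic maximum dimension

`auto_dmax()` brackets `Dmax ∈ [2Rg, 4Rg]` (Rg from `autorg()`) and scans
25 candidates. Three diagnostics separate truncated from admissible
solutions: (a) feasibility — below the true dimension the fit cannot
reproduce the data and χ²ᵣ rises sharply above the bracket-wide floor
(threshold `1.5·min + 0.3`); (b) the normalized end slope
`|p′(Dmax)|·Dmax/max|p|` must not exceed 1 — a distribution cut off by a
too-small Dmax terminates steeply; (c) at most 1% of the |p| mass may lie
beyond `0.9·Dmax` — a too-large Dmax leaves a spurious outer tail. The
smallest admissible candidate is sharpened by bisection. On exact data
with realistic error columns this lands within 0.5% (sphere) and 1.6%
(two-sphere dumbbell) of the true dimension, and within a median 0.4% on
2%-noise spheres. When no candidate passes the shape diagnostics the
feasible solution with the best total estimate is returned.

Alternatives were examined and rejected: a pure χ²-elbow rule
systematically lands 5–6% low (the outermost few percent of p(r) mass is
within noise of zero), and a tail-crossing rule on a generous-Dmax
solution is destabilized by regularization ripples.

### Size distributions

For polydisperse sphere systems, `size_distribution_solve()` inverts
`I(s) = Σⱼ Dᵥ(Rⱼ)·V(Rⱼ)·Φ²(sRⱼ)·ΔR` under the same first-difference
smoothness penalty plus non-negativity (Lawson–Hanson active-set NNLS on
the α-augmented system). Here automatic α uses the discrepancy principle
— the largest α whose χ²ᵣ stays within `1.3·min + 0.2` of the
unregularized optimum — because the radius-grid discretization prevents
χ²ᵣ from reaching 1 on sharply monodisperse data, which strands the
perceptual total in oversmoothed territory.

## Invariants and molecular weight

`porod_volume()` estimates the flat background K and the Porod amplitude
A from the linearity of `s⁴I` versus `s⁴` over the top half of the
measured range. Ideal sharp-interface bodies oscillate around the Porod
asymptote with full amplitude, so the background term is retained only
when it halves the residual sum of squares; otherwise K = 0 and A is the
plain mean, which averages the oscillation instead of leaking it into a
spurious background. The invariant assembles three pieces:
`Q = ∫₀^{s₁} s²·I_Guinier ds + ∫ data + A/smax` — the unmeasured origin
completed with the Guinier model, and the unmeasured high-angle region
with the fitted `A/s⁴` asymptote. Omitting the tail completion would lose
~13% of Q for a 30 Å sphere measured to 0.5 Å⁻¹; with it, sphere volumes
are recovered within ~1% across 15–60 Å radii.

`mw_from_vc()` truncates `∫ sI ds` at 0.3 Å⁻¹ by default (common practice
for this estimator) with the same Guinier origin completion, and maps
`QR = V_c²/Rg` to mass through the published power law (protein:
`MW = QR/0.1231`; nucleic acid: `MW = (QR/0.00934)^0.808`). The constants
live in `inst/extdata/coefficients.yaml` and can be replaced wholesale via
`sas_coefficients(path)`. `mw_from_mow()` computes the apparent Porod
volume at a truncated cutoff without background subtraction or tail
completion and applies a truncation-correction polynomial; the packaged
correction defaults were calibrated on synthetic uniform spheres of
20–60 Å radius (quadratic fit of the true/apparent volume ratio against
the cutoff; residual spread ±8% across that size range) and are marked as
such in the configuration — users targeting the original published
correction should substitute its coefficients. The residue masses and
partial specific volumes behind `sequence_stats()` are consensus
literature values; note that the single-letter keys are quoted in the
YAML because bare `Y`/`N` would parse as booleans.

`useful_angular_range()` expresses `s·I(s)` in the cardinal (Whittaker)
sinc basis with channels at `s_k = kπ/Dmax`, whose coefficients are the
channel values themselves. A channel counts as reliably determined only
if the data inside its own sampling lobe (`|Dmax·s − kπ| < π`) pin it at
2σ. The locality is deliberate: a joint fit would credit channels beyond
a noise wall through band-limited extrapolation from the precise
low-angle region (numerically this reaches t-values in the hundreds),
which is exactly what a useful-range diagnostic must not do. Joint-fit
coefficients are still reported for reference.

## Form factors, mixtures and component counting

Sphere, core–shell sphere and dumbbell intensities are closed-form;
cylinder, core–shell cylinder, ellipsoid of revolution and parallelepiped
are orientation-averaged by Gauss–Legendre quadrature (order 64, double
quadrature for the parallelepiped), converged to better than 1e-6
relative at the default order for the sizes and angular ranges used here.
The hard-sphere Percus–Yevick structure factor is the standard closed
form with a series fallback below `2sR = 0.05`, applied to the mixture
total in the decoupling approximation — the only interparticle model
offered. Size dispersion integrates the designated size parameter of each
body kind over a Gaussian (15-node Gauss–Hermite, negative sizes clipped)
or lognormal (log-grid trapezoid) distribution.

`fit_body()` and `fit_mixture()` optimize log-transformed dimensions
(and softmax-reparameterized fractions on the simplex) by seeded
multi-start Levenberg–Marquardt with an analytic profile over the scale.
Sharp interference minima ripple the least-squares surface at the
sub-percent scale and can stall trust-region steps in micro-minima;
a deterministic coordinate-wise grid-plus-golden polish over a ±8%
log-window, followed by a final local refit, recovers the valley floor.
When only fractions are free and no structure factor is present the
problem is linear and is solved exactly by NNLS
(`oligomer_fractions()`), with an optional sum-to-one constraint imposed
through a heavily weighted augmented row, linearized covariances from
the passive set, and a rank-deficiency warning when components are
collinear.

`svd_rank()` counts singular values above a noise floor calibrated from
50 seeded matrices of the same shape filled with the curves' own σ (or
unit normal when σ-normalized), scaled by 1.5. The floor uses the median
noise singular value, so a component must clear the bulk of the noise
spectrum, not its edge.

`debye_intensity()` evaluates the exact pairwise sum
`Σ wⱼwₖ sinc(s·dⱼₖ)`; beyond 2×10⁵ pairs the sum is accumulated on a
0.01 Å distance histogram, a phase perturbation below `0.005·s` radians —
four orders of magnitude under the tolerances used anywhere in the
package.

## The synthetic-data generator

`simulate_curve()` adds Gaussian noise with
`σ(s) = level·(I + background)·(1 + (s/smax)^exponent)` — by default 2%
relative at the low-angle end, doubling toward the end of the range
(exponent 1), emulating the error growth of background-subtracted
counting data at a modern beamline. Gaussian rather than Poisson noise
matches high-count practice and keeps the χ² calibration exact: the σ
column stores the exact generating value, so tests can compute exact
z-scores. Every generator seeds a local RNG and restores the caller's
stream. `dilution_series()` multiplies a body curve by concentration and
a Percus–Yevick factor with `η = interaction·c`, reproducing the
repulsive low-angle suppression that motivates merging and
infinite-dilution extrapolation.

Two idealizations matter when transferring test results to real data.
First, ideal geometric bodies have perfectly sharp interference minima;
with a purely proportional error model those points would carry
near-zero σ and unbounded statistical weight, so noise-free test fixtures
add a 0.1% intensity floor to σ, as any real detector does. Second, the
generator produces neither inter-frame radiation damage, buffer-subtraction
artifacts, nor smearing; passing tests demonstrate the correctness of the
estimators under their stated noise model, not robustness to systematics
outside it.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run: exact longest-run
enumeration to n = 16; 2000 simulated null pairs (n = 100, 2% noise) for
the sign-test calibration; 1000 pairs (n = 200) for the χ² mean; 100
noisy spheres for automatic-Rg robustness and 20 for automatic-Dmax;
~4200-bead Debye spheres; and single noise-free curves of 80–250 points
for all closed-form comparisons. The full suite completes in roughly two
minutes on one CPU.

## Known limitations

Slit-smearing, multi-dataset simultaneous fits, time/frame-series
handling and 2D reduction are out of scope. The automatic Dmax search
assumes a mostly compact particle (bracket `[2Rg, 4Rg]`); strongly
elongated or flexible systems can push the true dimension beyond 4Rg.
The MoW-style truncation correction is a synthetic-sphere calibration,
not the original published fit. Only the hard-sphere Percus–Yevick
structure factor is available, in the decoupling approximation; strongly
attractive or charged systems need models outside this package.
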