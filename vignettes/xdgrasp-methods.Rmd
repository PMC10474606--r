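---
title: "Respiratory-resolved 4D-MRI reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-resolved 4D-MRI reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stargrasp)
```

This vignette explains the science implemented by `stargrasp`, the
assumptions behind each stage, the tunable parameters, and the numerical
and design choices made where the problem left the design open. It states
no empirical results beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## The reconstruction model

A golden-angle radial stack-of-stars acquisition samples 2D radial spokes
in the kx-ky plane while phase-encoding the third axis (kz) on a
Cartesian grid. Because breathing is quasi-periodic and each spoke is
acquired at a known time, spokes can be retrospectively sorted into
respiratory bins and one image reconstructed per bin. Undersampling
within each bin is compensated by the XD-GRASP model: per slice,

$$\hat d = \arg\min_d \; \lVert W(F S d - m)\rVert_2^2
  + \lambda \lVert T d\rVert_1 ,$$

with $S$ the coil sensitivities, $F$ the non-uniform Fourier transform
onto the bin's spoke locations, $W$ a diagonal square-root
density-compensation weighting, and $T$ the first-difference operator
along the respiratory-bin axis. The TV term along bins exploits that
adjacent motion states are similar almost everywhere; it is
*non-circular* because amplitude-ordered bins run from one breathing
extreme to the other and are not a cycle.

The kz axis is fully Cartesian, so a centred orthonormal inverse FFT
along kz decouples the 3D volume into independent per-slice 2D problems.
Slices are solved in parallel with no shared state; results are deposited
by slice index, which makes the 4D volume bitwise independent of the
worker count and of the assignment mode (contiguous blocks or a
round-robin queue emulation). kz oversampling (more encodes than slices
in the prescribed field of view, factor 1.61 in the emulated clinical
protocol) is removed by central cropping after the kz FFT.

## Solver

Fletcher-Reeves nonlinear conjugate gradient with Armijo backtracking
(initial step 1.0, shrink 0.6, sufficient decrease 0.01, at most 150
backtracks), run for a fixed budget of 8 iterations; these are the
constants of the reference implementation lineage of this algorithm
family, which states only "conjugate gradient" without further detail.
An early-termination knob (`early_stop_tol`) exists because the per-slice
objective is local and benefits from early stopping, but it is off by
default so the iteration budget is deterministic.

Two implementation points matter numerically:

* **Initialisation and operator scale.** The initial image is
  $d^0 = A^H y$ with $A = WFS$ and $y = Wm$: the density-compensated
  (filtered) backprojection. Each bin's weights are normalised by their
  sum inside the encoding (`slice_encoding(..., normalize = TRUE)`), so
  the point-spread function of $A^H A$ has unit peak and $d^0$ lands on
  the image scale. Without this, the adjoint image is off by orders of
  magnitude and the fixed iteration budget is spent correcting scale
  rather than structure.
* **Line search cost.** The fidelity term is an exact quadratic along any
  search direction, so each line search computes one forward transform
  (of the direction) and then evaluates candidate steps through the
  quadratic coefficients plus the cheap image-domain TV term. Backtracks
  therefore cost no additional transforms.

The L1 norm is smoothed as $\sqrt{|x|^2+\varepsilon}$ with
$\varepsilon = 10^{-15}$ (the lineage's value); at image scales of order
one this is indistinguishable from $|x|$. $\lambda = 0.02$ is made
scale-free by multiplying with $\max|d^0|$ per slice
(`lambda_scale = "auto"`); whether the original protocol's value is
absolute or normalised is not documented anywhere we know of, so the
absolute mode remains available.

## Self-gating

The DC readout sample (kx = ky = 0) of every spoke measures the total
transverse magnetisation seen by each coil, which respiration modulates.
The *baseline* method takes the magnitudes of this navigator across
(kz, coil) as features, mean-centres them, and runs PCA over spokes. The
component used is **not** blindly the first one: each component's score
series is Fourier-analysed and the component with the largest spectral
power fraction inside the respiratory band (default 0.1-0.5 Hz, the
physiological breathing range) is selected. The selected score is
standardised to zero mean, unit variance.

*ADERS* additionally removes the angle-dependent baseline that
golden-angle sampling imprints on the navigator: per (kz, coil) feature,
magnitudes are ordered by spoke angle and a centred moving average over
`window = 11` angle neighbours is subtracted (the window shrinks
symmetrically at the ends of the angle range). Each coil is then scored
by the respiratory-band power fraction of its leading principal
component, the `floor(n_coils/2)` worst coils are dropped, and the PCA
proceeds over the surviving coils. The coil-quality metric of the
original angle-correction method is not published in detail; band-power
fraction is our documented stand-in, and the moving average is applied
per (kz, coil) feature (the alternative — one average over all features —
is not distinguishable from the available description).

**Sign convention.** A surrogate extracted by PCA has an arbitrary sign.
We orient every signal so its skewness is non-negative: breathing spends
more time near end-exhale, producing a plateau at one extreme and hence a
skewed amplitude distribution, so this rule is deterministic and
reproducible — but it cannot know which physical extreme is inspiration.
Downstream comparisons against ground truth therefore use |r| and
displacement magnitudes.

## Binning

*Amplitude (equal-count) bins*: spokes sorted by decreasing surrogate
value (ties broken by acquisition time) are cut into `n_bins` contiguous
groups whose sizes differ by at most one, larger groups first; 831 spokes
into 8 bins gives seven bins of 104 and one of 103. *Overlapping bins*
(ORB) cut the sorted spokes into `2 n_bins` half-groups and give bin *i*
the half-groups `{2i-2, ..., 2i+1}`: every interior spoke lands in exactly
two adjacent bins while the two extreme half-groups (deepest inhale and
exhale) stay single-membership, and when `2 n_bins` divides the spoke
count the extremum bins hold 3/4 of an interior bin. This half-group rule
is our construction; it is the simplest balanced scheme consistent with
the verbal description "each spoke contributes to two adjacent bins
except at the extremes", and it is asserted as such by the tests.

## Non-uniform transforms

`nufft_plan()` implements type-2 (image to non-uniform samples) and
type-1 (its exact adjoint) by interpolation on an oversampled FFT grid.
Three numerical choices:

* **Min-max interpolation weights.** For the configured support width
  (4 cells at oversampling 2.0, 5 cells at 1.25 — the widths standard
  NUFFT libraries select for a 1e-3 tolerance), the per-sample
  interpolation weights are least-squares optimal given the scaling: a
  small Toeplitz system per axis, solved at plan time. The scaling
  (deapodization) itself is refined by a few alternating least-squares
  passes on a fine frequency grid, seeded with the Kaiser-Bessel
  transform. The kernel therefore only initialises the optimisation; the
  resulting operator outperforms plain Kaiser-Bessel gridding at low
  oversampling.
* **Tolerance-guaranteeing grid.** The aliasing floor of a width-w
  interpolator at per-axis oversampling $\sigma$ behaves like
  $\exp(-\pi w \sqrt{1 - 1/\sigma})$. The plan starts from the smallest
  even grid of at least $\sigma n$ and enlarges it by two cells at a time
  until a conservative calibration of that model (factor $2\sqrt2$) meets
  the requested tolerance. At oversampling 2.0 the grid is exactly $2n$;
  at 1.25 with width 5 the rule settles slightly above the nominal grid.
  The support width — the per-sample cost that dominates gridding time —
  is never changed.
* **Exact adjoint pair.** Type-1 is the transpose of the type-2 spreading
  matrix combined with the adjoint FFT, so adjoint tests hold to machine
  precision and the conjugate-gradient model is internally consistent.

`nudft_plan()` is the exact direct-summation NUDFT ($O(MN)$, with a
resource guard), organised as two BLAS-friendly matrix products. It is
the oracle for all accuracy tests, the engine of the simulator, and a
drop-in reference engine for the solver (`engine = "nudft"`), which is
how the package reproduces the implementation-equivalence comparison:
fast and reference reconstructions differ only in the transform.

Transform applications are counted (`nufft_call_count()`), which turns
"reconstruction work grows linearly with the number of respiratory bins"
into an exact operation-count assertion instead of a wall-clock claim.

## The synthetic-data generator

The simulator emulates the acquisition the pipeline targets: a
volumetric golden-angle stack-of-stars scan of a breathing abdomen.

* **Trace**: $\sin(2\pi f t) + \text{drift}\cdot t + \text{noise}$,
  rescaled to [0, 1], sampled once per spoke at the clinical cadence
  (287 s for 831 spokes). Defaults: f = 0.25 Hz (a normal breathing
  rate), noise 0.05, drift 0.003 per second — over a full scan the drift
  accumulates to roughly 40% of the breathing amplitude, a realistic slow
  baseline shift that still leaves the surrogate breathing-dominated (a
  drift that dwarfs the sinusoid would make any self-gating method track
  the drift instead).
* **Phantom**: ellipses whose centre, axes and rotation are affine in the
  respiratory amplitude; the default phantom is a static body oval, a
  superior-inferior translating organ with a co-moving lesion (excursion
  0.12 of the FOV), and a static posterior disc.
* **Coils**: complex Gaussian-bump sensitivities with smooth linear phase
  ramps, 8 coils by default (an anterior/posterior surface array), RSS
  bounded away from zero.
* **k-space**: rendered per spoke at that spoke's trace amplitude,
  multiplied by each coil map, orthonormally FFT'd along z, and evaluated
  per kz plane by **exact NUDFT**. Simulating with the exact transform
  (never the gridding NUFFT) avoids the inverse crime: reconstruction and
  simulation share no approximation. kz oversampling is emulated by
  rendering the phantom into the central slab of a longer z grid.

What the generator does *not* emulate: MR contrast and relaxation, fat
suppression, partial-echo readout asymmetry, gradient-delay trajectory
errors, thermal noise correlations between coils, and non-rigid
deformation beyond affine ellipse motion. Passing tests on this phantom
therefore demonstrate the correctness of the *reconstruction machinery*
— operators, gating, binning, solver, scheduling — not robustness to
every physical effect present in patient data.

## Problem sizes used by the tests

Module tests run on 16-48 voxel grids with tens to hundreds of spokes.
The shared fixtures are a 32x32, 2-slice, 4-coil, 160-spoke acquisition
(solver and metrics tests) and a 32x32, 2-slice, 8-coil, 831-spoke
acquisition at the full clinical cadence (gating tests). The
implementation-equivalence check reconstructs a 64x64, 8-slice, 4-coil,
400-spoke, 4-bin acquisition twice (fast NUFFT vs exact NUDFT) and
compares mean SSIM; these sizes keep the exact-NUDFT reference tractable
on a single CPU while preserving the undersampling regime (about 100
spokes per bin for a 64-pixel grid) in which the method operates.

## Known limitations

* Coil-sensitivity maps are an input (the simulator provides ground-truth
  maps); no vendor-grade estimation method is bundled.
* The respiratory surrogate's orientation is fixed by a statistical
  convention (non-negative skewness), not anatomy; bin 1 is one breathing
  extreme, not guaranteed to be inspiration.
* Partial-Fourier kz data are zero-filled on read; no homodyne/POCS
  completion.
* The raw-data container is the package's own self-describing format
  (JSON header + binary payload); vendor raw formats are out of scope.
* The parallel scheduler targets a single shared-memory machine
  (fork-based workers); there is no GPU backend and no multi-node
  distribution.
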