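---
title: "Small-field dosimetry with smallfieldr: models, parameters and design choices"
author: "smallfieldr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-field dosimetry with smallfieldr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallfieldr)
```

## The problem

Radiosurgery cones of a few millimetres diameter are at the edge of what
detectors can measure. Around and below 5 mm field diameter, three effects
conspire against any real detector:

* **volume averaging** — a sensitive volume of finite diameter (here a
  1.5 mm diode disk) averages a strongly peaked dose distribution and
  under-reads the axis dose;
* **density perturbations** — the detector housing and the chip material
  are denser than water and scatter additional dose into the sensitive
  volume, causing over-response;
* **loss of lateral charged-particle equilibrium**, which makes all of
  this field-size dependent.

The standard remedy is a field-size-dependent output correction factor
\(k\) applied to the measured output ratio. This package implements the
full analysis chain needed to characterize such a beam and to derive and
apply those corrections: a convolution beam model with
deconvolution-derived virtual fluence sources, beam-scan and film
analytics, the perturbation-factor calculus, and the parametric
output-factor fit — together with a synthetic-data generator that
emulates every input with known ground truth.

## The convolution beam model

The lateral dose distribution at a fixed water depth is modelled as

\[ D(r) = \psi(r) * K_D(r), \]

a 2D convolution of a radially symmetric virtual photon fluence
\(\psi(r)\) with a radially symmetric dose-deposition kernel
\(K_D(r)\). `convolveRadial()` evaluates this on a uniform Cartesian
grid (default spacing 0.1 mm, the step size at which detector signals
are typically simulated) by zero-padded FFT. Two numerical points
matter:

* **Sharp field edges.** A top-hat fluence is discontinuous; a plain
  cell-center Riemann sum concentrates its quadrature error at the edge.
  The engine rasterizes the source with sub-cell averaging (5×5 by
  default) and computes the convolution on an internally refined grid
  (factor 2 by default) before decimating back. With these defaults the
  axis and off-axis dose agree with a 0.02 mm brute-force quadrature to
  better than 0.1% of the axis dose.
* **Kernel sampling.** Kernels are stored as radial samples and placed
  on the grid by a shape-preserving cubic (`monoH.FC`), which avoids the
  convexity bias of linear chords. Kernels should be sampled with
  spacing at most a quarter of their narrowest width; a discrete impulse
  (identity) kernel is also supported exactly.

Kernel normalization is stored, not forced to one: the stored integral
is computed from the same rasterization the engine uses, so a uniform
fluence of level \(c\) maps to a uniform dose \(c\) times the stored
integral, exactly. All downstream metrics are normalization independent.

`decomposeSteps()` converts any sampled radial fluence into a
superposition of weighted step functions — the representation in which
virtual sources are typically handed to a Monte-Carlo dose engine — by
equal subdivision of the fluence support, with the plateau of each bin
matched at its center.

## Deconvolution: deriving the virtual source

Given a measured lateral dose profile and a kernel, `vanCittert()`
recovers the fluence by the van-Cittert iteration

\[ \psi^{(k+1)} = \psi^{(k)} + \alpha\,(D - K * \psi^{(k)}),
   \qquad \psi^{(0)} = D , \]

where the forward operator is the full radially symmetric 2D
convolution restricted to radial functions (precomputed once as a dense
matrix over a hat-function basis, so 500 iterations cost milliseconds).
Defaults are \(\alpha = 1\), at most 500 iterations, a relative L2
residual tolerance of \(10^{-4}\), and a non-negativity clip after each
iteration, enforcing the physical \(\psi \ge 0\). No smoothing is ever
applied silently.

Two properties of this inverse problem are worth understanding:

* **Residual vs. fluence error.** The dose-space residual
  \(\|D - K*\psi\|_2/\|D\|_2\) converges quickly (well below 1% within
  200 iterations for a blurred 3 mm top-hat). The fluence itself,
  however, can never fully recover a discontinuous edge: frequencies at
  which the kernel's transfer function is essentially zero are
  unrecoverable at any iteration count, so a recovered top-hat retains a
  smoothed edge (an L2 fluence error of order 15% against the ideal
  discontinuous source) even when the re-convolved dose matches the
  measurement to a fraction of a percent. Convergence reporting is
  therefore based on the residual, and validation (`validateForward()`)
  compares re-convolved dose against measurement.
* **Noise.** With noisy data the plain iteration eventually amplifies
  noise. The `smoothingWindow` setting applies a moving average to the
  *correction term* each iteration — the regularized van-Cittert
  variant. Smoothing the iterate instead would accumulate blur (200
  iterations of a 5-sample window are equivalent to a ~2 mm Gaussian)
  and biases the solution; smoothing the correction leaves the fixed
  point consistent with the data while keeping high-frequency noise out
  of the update. For 0.5% profile noise, a 5-sample window holds the
  re-convolved dose within about 0.5% of the noiseless truth.
  A useful stopping rule for noisy data is to set `residualTolerance`
  near the expected noise floor (discrepancy principle).

## Scan analytics

`profileFWHM()` and `profilePenumbra()` implement the operational
definitions: distance between the 50% crossings of the normalized
profile (the dosimetric field size), and the 20–80% distance on each
edge. Crossings are located by linear interpolation between bracketing
samples; where a noisy shoulder produces several crossings the outermost
are used, deterministically. The profile center is the midpoint of the
50% crossings, which re-centers measured scans the way a field-aligned
detector setup would. No smoothing is applied by default — a 3 mm
profile is only ~30 samples wide at 0.1 mm and any smoothing biases its
penumbra.

One ordering deserves a note: for the 2D convolution of a disk with a
radial kernel, the FWHM is *not* bounded below by the disk diameter. The
axis dose loses \(e^{-R^2/2\sigma^2}\) of its plateau value, which
lowers the 50% level, and the convex field boundary pushes the edge
value below half — so FWHM approaches the diameter only as the kernel
narrows (e.g. 2.84 mm for a 3 mm disk with a single \(\sigma=0.5\) mm
Gaussian). Realistic kernels with a broad scatter tail (see below)
depress the axis dose further and land the FWHM at the nominal 3.0 mm.

`pddMetrics()` locates the depth of dose maximum on a locally smoothed
depth curve (default 5 samples, with parabolic sub-sample refinement)
and evaluates percentage dose at requested depths relative to the
smoothed maximum. Locating the maximum of a flat build-up peak under
noise is intrinsically scatter-limited (about ±0.2 mm at 0.2% noise);
wider smoothing windows would reduce the scatter but bias the estimate
toward the slowly falling side of the asymmetric peak, so the default
stays narrow and unbiased.

## Detector response and perturbation factors

The perturbation calculus follows the step-wise detector-model
decomposition used in Monte-Carlo studies of small-field diodes: from
the full detector model (signal \(M_{diode}\)), to the housing replaced
by water (\(M_{si,vol}\)), to the sensitive chip also replaced by water
(\(D_{w,vol}\)), to a 0.2 mm point scoring voxel (\(D_{w,point}\)).
Ratios of consecutive steps, normalized to the 25 mm
machine-specific-reference (msr) field, give \(P_{housing}\),
\(P_{sens}\) and \(P_{vol}\); their product telescopes *exactly* to the
total correction \(k\), an algebraic identity
`perturbationFromSignals()` preserves to machine precision.

The package does not perform radiation transport. The published factors
for the characterized cone sizes ship as data
(`packagedFactorTable()`), with unreported components stored as absent
rather than interpolated. What *is* computed is the geometric part of
the volume-averaging factor: `volumeAverage()` averages a dose map over
the sensitive disk using exact disk/cell overlap areas (error second
order in grid spacing; the quadratic-profile closed form is met to
\(10^{-4}\)), and `pVolGeometric()` forms the point-to-disk double
ratio. With the synthetic 3 mm and 25 mm beams this geometric estimate
lands at about 1.08 — consistent with the published 1.075, which
includes transport effects beyond geometry, and the comparison is
treated as a bracket, not an equality.

`emulateSignalProfile()` is a parametric detector emulator: disk
averaging plus a field-size-interpolated density over-response (the
reciprocals of the packaged housing and chip factors). It reproduces the
characteristic observation that a finite diode scans a slightly broader
profile than film, with broadening monotone in the sensitive diameter.

## Film dosimetry

The film pipeline fixes the response variable to net optical density in
the red channel, \(netOD = \log_{10}(I_{unexposed}/I_{exposed})\) — the
dominant convention for this film type; the calibration maps netOD to
dose through a least-squares cubic over the 0–2 Gy design, with
monotonicity verified on the calibrated range and fits failing loudly
otherwise. Scan noise is suppressed by a 2D median filter (reflected
edges); dose maps inherit their spacing from the scanner resolution
(25.4/dpi mm). Film output factors are ratios of median-filtered central
values (5×5 pixels after a 5×5 filter), centered via the 50% crossings
of each map's orthogonal profiles, with the k=1 uncertainty taken as the
standard deviation of the mean over repeat films. Pixels are predicted
within the calibrated range plus a small netOD slack so that noise at
the range ends is not half-clipped, which would otherwise bias doses
near 0 and 2 Gy.

## Output factors

`outputRatio()` forms the detector output ratio
\(OR = M^{clin}/M^{msr}\) per monitor unit with type-A (k=1)
uncertainties propagated in quadrature;
`correctedOutputFactor()` multiplies by the total correction.
`fitOFCurve()` fits the saturating two-component field-size curve

\[ OF(s) = p\,\frac{s^{\,n}}{a^{\,n} + s^{\,n}}\,
   \bigl(1 - e^{-b s}\bigr) \]

by bounded Levenberg–Marquardt from five deterministic starts
(half-saturation 2–10 mm, Hill exponent 1–3), keeping the lowest
residual sum. The printed rendering of this fit function in the
literature this parameterization follows is typographically garbled; the
form above is the standard reading consistent with its parameter list
and saturation behaviour, and it is deliberately isolated in the single
function `ofCurve()` so an alternative reading can be swapped in at one
place.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth; no
analysis stage reads the truth.

* **Lateral profiles** (`makeDoseProfile()`, `makeDoseMap()`): a
  top-hat fluence of the nominal cone diameter convolved with a
  two-Gaussian kernel — narrow core plus broad scatter tail, the
  simplest family that reproduces realistic small-field penumbras. The
  convolution of a disk with a 2D Gaussian has a closed form (the
  noncentral-\(\chi^2_2\) tail), so the generator's truth values (FWHM,
  penumbra, axis dose) come from root finding on an analytic curve, not
  from the package's grid engine. Defaults: core \(\sigma = 0.8946\) mm,
  tail \(\sigma = 2\) mm at 8% weight, calibrated once so the 3 mm cone
  at 7 mm depth has FWHM 3.0 mm and 20–80% penumbra ≈ 1.35 mm — the
  measured values for such a beam — with a depth table of kernel-width
  multipliers reproducing the measured field-size growth (3.0 → 4.8 mm
  over 7 → 250 mm depth; the multipliers at the five characterized
  depths are interpolated linearly in between, a modeling choice). The
  same calibration reproduces the measured depth trend of the penumbra
  (1.3 → 2.3 mm) without further tuning.
* **Depth curves** (`makePDD()`): the build-up/fall-off family
  \(A(1-e^{-\mu_1 z})e^{-\mu_2 z}\) with \((\mu_1,\mu_2)\) solved at run
  time so the analytic depth of maximum and percentage dose at 100 mm
  match the characterized anchors (4.8 mm / 35.6% at 3 mm diameter,
  5.0 mm / 36.7% at 4 mm, 7.8 mm / 41.2% at 25 mm), interpolated
  linearly in cone diameter in between.
* **Films** (`makeFilmSet()`): a monotone ground-truth cubic from netOD
  to dose (reaching ≈2 Gy at netOD 0.56, a realistic red-channel
  response), unexposed intensity 40000 of the 16-bit range, 1%
  multiplicative pixel noise, 600 dpi, and 16-bit quantization. The
  truth cubic lies in the calibration fit's model class, so the
  zero-noise round trip is exact up to quantization.
* **Detector readings** (`makeORSeries()`): true output factors from a
  frozen parameter set (fitted once to the published output factors of
  the characterized cones) divided by the interpolated packaged
  correction, times 0.5% multiplicative noise — so applying the
  correction round-trips the truth by construction.
* Scan noise defaults to 0.5% additive (short-dwell detector scans),
  PDD noise to 0.2%. All generators are pure functions of their
  parameters and a seed.

What the generator does **not** emulate: Monte-Carlo batch-noise
structure, scanner artifacts (vignetting, lateral response), beam
inclination, asymmetric sources, contaminant-electron build-up effects
and depth-dependent kernel shape changes beyond a global width scaling.
Passing tests on synthetic data therefore demonstrate the correctness
and numerical behaviour of the analysis chain under controlled,
realistic conditions — not the accuracy of any physical measurement.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script run at the sizes the methods
are designed for: 0.1 mm grids of roughly 160×160 cells for dose maps,
81-point radial profiles for deconvolution (500 iterations), million-
point Monte-Carlo disk-average oracles, film fixtures of 48–512 pixels
per side at 150–600 dpi with 5 repeats, and 20 replicate fits for the
output-factor curve. Degenerate inputs (all-zero profiles, missing level
crossings, non-positive signals, non-monotone calibrations, off-grid
disks) fail with explicit errors rather than silent repair.

## A worked example

```{r example}
# generate a 3 mm scan at 7 mm depth and analyze it
p <- makeDoseProfile(beamSpec(3), depth = 7, seed = 1)
unlist(profileMetrics(p$profile)[c("fwhm", "penumbraLeft", "penumbraRight")])

# the published perturbation components at 3 mm and their product
tab <- packagedFactorTable(3)
c(k_total = tab$p_housing * tab$p_sens * tab$p_vol)

# correct a measured output ratio
correctedOutputFactor(0.447, 1.034)
```

## Known limitations

* Single-depth kernels only; no photon spectrum or transport.
* The deconvolution assumes radial symmetry; asymmetric or tilted
  sources are out of scope.
* Published perturbation factors are point data at four cone sizes;
  interpolation of the total correction between them is linear and the
  unreported components are never imputed.
* The film model is single-channel (red); multichannel dosimetry and
  scanner lateral-response corrections are not implemented.
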