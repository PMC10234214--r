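---
title: "Aggregate morphometry and bioink rheology with bioinkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregate morphometry and bioink rheology with bioinkr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioinkr)
```

## What this package models

Suspension cultures of human induced pluripotent stem cells spontaneously
form near-spherical multicellular aggregates (hAs). Two routine quantitative
tasks surround such cultures, and `bioinkr` implements both:

1. **Morphometry of brightfield images.** Aggregates appear as dark,
   near-circular blobs on a light background. The package segments them with
   a multi-pass rough circular Hough transform, then reports diameters,
   two circularity scores, distribution summaries (median, IQR, fractions
   past clinically motivated thresholds) and rank-sum comparisons between
   conditions, plus fold-expansion bookkeeping for the culture itself.
2. **Constitutive rheology of compacted aggregate bioinks.** Centrifuged
   aggregate slurries behave as jammed granular yield-stress materials.
   The package forward-evaluates and fits a thixotropic Herschel-Bulkley
   flow model and a fractional Jeffrey viscoelastic model, extracts yield
   stress, critical strain, loss tangent and recovery timescales, and
   applies the parallel-plate rim-stress correction.

A seeded synthetic-data module generates ground-truthed images and
rheograms, so every downstream stage is benchmarked without any external
dataset.

## Segmentation: rough circular Hough transform

A grayscale image is first binarized with a global threshold on the
0-to-1 intensity scale; pixels darker than the threshold are foreground.
The threshold is conventionally kept in a narrow window, 0.4-0.6, and
defaults to its midpoint 0.5; values outside the window need an explicit
override. On the foreground, votes are accumulated over circle hypotheses
$(A, B, R)$ satisfying $(x-A)^2 + (y-B)^2 = R^2$: a foreground pixel at
Euclidean distance $d$ from a candidate center votes at the integer radius
bin $\mathrm{round}(d)$, i.e. with a $\pm 0.5$ px annulus tolerance.

Evaluating the accumulator at every pixel is quadratic in the foreground
size and contributes nothing away from blob centers, so candidate centers
are proposed at local maxima of the mask's distance transform (one per
convex lobe) and refined over a small window; the votes at every evaluated
center equal the full accumulator's by construction, and `hough_votes()`
exposes the exact accumulator for arbitrary centers (it is oracle-tested
against a brute-force double loop). Because the vote peak over centers is a
discretization plateau, the reported center is the plateau centroid, which
is what makes sub-pixel center accuracy possible.

Radius selection uses two rules:

- **Support threshold.** A radius is only a candidate if its votes reach
  `accept_frac` (default 0.5) of the ideal circle perimeter $2\pi R$ —
  at least half the rim must be present. This rejects speckle and stray
  annulus votes contributed by *other* aggregates at implausible radii.
- **Sensitivity rule.** Among supported radii, those with votes within
  `sensitivity` times the maximum are eligible and the largest eligible
  radius is returned. Sensitivity 0 is the pure vote argmax; sensitivity 1
  always takes the largest supported radius; the rule is monotone in
  between, so sensitivities near 1 favour larger radii on split votes.

The default schedule runs five passes with radius windows 20-200, 40-200,
60-200, 80-200 and 90-200 px and sensitivities 0.72, 0.76, 0.80, 0.88,
0.92; later passes ignore small features and lean larger. Since the
accumulator depends only on the mask, the profiles are computed once and
each pass only re-applies its window and sensitivity. Repeat identifications
across passes are collapsed by `dedupe_detections()`: two detections are
duplicates when their centers are closer than half the smaller radius or
when at least 60% of the smaller disk lies inside the larger; the
highest-vote detection wins (ties: larger radius, then earlier pass), and
the operation is idempotent.

Numerical behaviour worth knowing: with exact pixel-center membership the
outermost annulus of a digitized disk is only partially covered and ring
pixel counts fluctuate on the lattice, so the raw vote argmax tracks the
true radius to about 1.5 px. The sensitivity rule, not the raw argmax,
determines the reported radius; on the synthetic benchmark (20 fields of 10
disks, radii 20-100 px, 1.5 px blur, noise sd 10) recall and precision are
at least 0.95 with center RMSE well under 1 px and radius RMSE under 1 px.

## Two circularity scores

The package deliberately implements two scores that disagree on purpose:

- `circularity_isoperimetric()` is the classic $4\pi A / P^2$: exactly 1
  for an ideal circle, $\pi/4 \approx 0.785$ for a square, strictly below
  the same-area circle for any ellipse. $A$ is the pixel count of the
  connected component under the detection center. $P$ is estimated from the
  traced boundary chain with Vossepoel-Smeulders weights (0.980 per
  isothetic step, 1.406 per diagonal step, $-0.091$ per corner): a raw
  boundary-edge count measures a digitized disk's perimeter as $\approx 8r$
  rather than $2\pi r$ and would bias the score to $\approx 0.62$, while
  the weighted chain keeps digitized disks within a few percent of 1 from
  radius 30 px up (sharp axis-aligned corners, as on a rendered square, are
  under-measured by ~3%, the known trade-off of smooth-boundary
  calibration).
- `circularity_harmonic()` reproduces the segmentation-time computation:
  the areas of the segmented region measured at radii $R-4$ and $R+4$ px
  are combined by their harmonic mean and divided by $\pi R^2$. A perfect
  disk of radius $r$ scores $2(r-4)^2/((r-4)^2+r^2)$ — about 0.917 at
  $r = 50$ px, approaching 1 as $r$ grows — and elongated or ragged regions
  score lower. This variant is the default for distribution reporting
  because it is the score the segmentation pipeline actually produces.

Both scores are invariant under whole-pixel translation and 90-degree
rotation, tested as such.

## Distribution summaries, comparisons and growth

`summarize_distribution()` reports median and IQR (type-7,
linear-interpolation quantiles — fixed and matched by a brute-force oracle
in tests) of diameters and circularity, and two inclusive fractions:
diameters $\le$ 300 µm (the size band favoured for downstream
differentiation) and circularity $\ge$ 0.73. The micron calibration
`um_per_px` is a required input: magnification alone does not determine the
pixel pitch, so the generator and segmentation work in pixels and
calibration is applied at reporting time. Diameter is $2R$ from the Hough
radius, the only radius the segmentation measures.

`compare_distributions()` is a two-sided Mann-Whitney rank-sum test with
midrank ties. For combined $n \le 20$ the p-value enumerates all
$\binom{n}{n_A}$ assignments of the pooled values — exact even under ties —
with the two-sided p defined as the permutation probability of a $U$ at
least as far from $n_A n_B / 2$ as observed; larger samples use the normal
approximation with tie and continuity corrections.

`fold_expansion()` corrects for sampled volume: cells removed at earlier
samplings (density at sampling times volume withdrawn) are added back to
each later day's total before taking the ratio to day 0, so sampling at
constant density leaves the fold unchanged.

## Thixotropic Herschel-Bulkley flow model

The steady-state stress of the compacted bioink is modelled as

$$\sigma(\dot\gamma) = \frac{\sigma_0}{1+\lambda\dot\gamma} + K\dot\gamma^n$$

with intrinsic yield stress $\sigma_0$ (Pa), structural-reconstruction
timescale $\lambda$ (s), consistency $K$ (Pa s$^n$) and flow index $n$.
$\lambda = 0$ recovers the classic Herschel-Bulkley law; positive $\lambda$
produces the non-monotonic steady stress characteristic of thixotropic
materials. `hb_flow_monotonicity()` decides the dichotomy from the sign
structure of the analytic derivative (bracketed root refinement on a
log-spaced grid) and returns the stress-minimizing rate; it is validated
against dense grid scans.

`fit_hb()` minimizes *log*-stress residuals — stresses span decades across
a 0.01-5 1/s sweep, and log residuals also match the multiplicative error
structure of rheometers — under bound constraints, with eight deterministic
Levenberg-Marquardt starts built from data scales (low-rate stress for
$\sigma_0$; a high-rate log-log regression for $K$ and $n$). No random
initialization: fits are reproducible given the data. Noiseless 20-point
curves are recovered to well under 1%; at 5% multiplicative noise the
median recovered $\sigma_0$ over 100 replicates stays within 10% of truth.

## Fractional Jeffrey viscoelastic model

Oscillatory sweeps of the bioink show $G' \gg G''$ with weak power-law
frequency dependence — not Maxwellian. The five-parameter fractional
Jeffrey model is two spring-pots in series (quasi-properties $V$, $G$;
orders $1 \ge \alpha \ge \beta \ge 0$) with a Newtonian dashpot $\eta_0$ in
parallel, accounting for residual media. With
$G_1^* = V(i\omega)^\alpha$ and $G_2^* = G(i\omega)^\beta$,

$$G^*(\omega) = \frac{G_1^* G_2^*}{G_1^* + G_2^*} + i\omega\eta_0,$$

whose real and imaginary parts give the storage and loss moduli. The
implementation uses the expanded real trigonometric forms; because printed
renderings of those expansions are easy to mis-group, the complex identity
above is the arbiter, and a property test checks agreement to $10^{-10}$
relative error over 1000 random parameter draws. Useful limits, also
tested: $\alpha = 1, \beta = 0, \eta_0 = 0$ is a single-mode Maxwell fluid
with relaxation time $V/G$; $\alpha = \beta$ is a single spring-pot with
constant loss tangent $\tan(\pi\alpha/2)$; $\eta_0$ adds exactly
$\eta_0\omega$ to $G''$ and nothing to $G'$.

`fit_fjm()` jointly minimizes summed squared log-residuals of both moduli.
The order constraint $\beta \le \alpha$ becomes a box constraint through
the internal parameterization $(\log V, \log G, \alpha, \beta/\alpha,
\eta_0)$; eight deterministic starts cover slow/fast relaxation and
zero/nonzero dashpot guesses, and standard errors on the natural parameters
come from the Jacobian by the delta method. Noiseless sweeps are recovered
to well under 2% per parameter.

Around the two constitutive models sit three protocol utilities:
`critical_strain()` (strain at which $G'$ first drops 10% — configurable —
below its low-strain plateau, interpolated in log strain; the experimental
observable is "yield near 3% strain", and the drop criterion, not the
visual kink, is what is returned), `fit_recovery()` (exponential rebuild of
$G'$ after flow cessation, $G'(t) = g_\infty - (g_\infty - g_0)
e^{-t/\tau_r}$, with constant traces flagged unidentifiable rather than
given an arbitrary timescale), and `parallel_plate_correct()` (single-point
rim-stress correction $\sigma_{\mathrm{true}} = \sigma_{\mathrm{app}}
(3 + \mathrm{d}\ln\sigma/\mathrm{d}\ln\dot\gamma)/4$ with central-difference
slopes, exact for Newtonian and power-law data, guarded against double
application). `check_hysteresis()` compares descending and ascending rate
sweeps pointwise and flags median discrepancies above 10%.

## Synthetic data: what it emulates and what it does not

`sim_field()` renders filled ellipses — ellipses rather than circles so
circularity has a controllable ground truth via the exact elliptic-integral
perimeter — dark (intensity 60) on a light background (200), Gaussian
optical blur of 1.5 px, additive camera-like Gaussian noise (sd 10), on a
1024 x 1024 px frame. Placement is rejection sampling with a hard cap of
10,000 attempts per aggregate and an explicit failure reporting the count
achieved. Aggregates never overlap and never touch the frame border.
Defaults (radii 20-100 px, mild ellipticity up to 1.3) describe a
well-stirred culture imaged at low magnification.

What the generator does *not* emulate: brightfield optics beyond a single
Gaussian blur (no defocus halos or rings), aggregate-aggregate fusion and
overlap, growth over culture days, or uneven illumination. Passing the
synthetic benchmark therefore demonstrates correctness of the segmentation
and measurement machinery on the imaging regime it assumes, not robustness
to every artifact of real microscopy.

`sim_flow_curve()` and `sim_frequency_sweep()` evaluate the two
constitutive models and multiply by unit-mean lognormal noise of a given
coefficient of variation — rheometer error scales with signal — seeded and
bitwise reproducible. The flow-curve defaults descend 5 to 0.01 1/s over 20
log-spaced points at $\sigma_0 = 29.9$ Pa; the sweep defaults cover 0.1-10
rad/s at 16 points with $G'$ in the kilopascal range and
$\tan\delta \ll 1$, the regime typical of compacted aggregate bioinks.

## Numerical choices and degenerate inputs

- Coordinates are (row, col), 1-based, pixel centers at integer positions;
  radii and all generator geometry are in pixels, microns enter only
  through `um_per_px`.
- Binarization outside [0.4, 0.6] requires an explicit override flag.
- Detection requires `radius_max` at most half the smaller image dimension.
- Empty fields, blank masks, degenerate (< 5 px) regions, constant stress
  curves, constant recovery traces, never-yielding amplitude sweeps and
  missing day-0 records all produce explicit errors or flagged reports,
  never silent numbers.
- All simulators restore the caller's RNG state; equal seeds give
  bitwise-equal outputs.

## Problem sizes used in the test suite

The shipped tests exercise the same procedures at sizes chosen to be
statistically meaningful while keeping a full run around a minute or two:
the segmentation benchmark uses 20 fields of 10 disks at 1024 px (the
acceptance script reruns it from scratch), oracle comparisons use 200-1000
random parameter draws, the noisy-recovery study uses 100 replicate
flow curves, and exhaustive rank-sum enumeration covers every group-size
split with combined $n \le 8$.

## Known limitations

- Fused or overlapping aggregates are not split (no watershed fallback);
  the duplicate criterion will keep the best-supported circle per lobe.
- The harmonic score depends on the detected radius; a mis-sized detection
  shifts the score even for a perfect disk.
- The thixotropic model is the steady-state law only; no structural
  kinetics ODE is fitted, so transient peak-hold viscosities are out of
  scope.
- The Mann-Whitney exact enumeration is $\binom{n}{n_A}$ and intentionally
  capped at combined $n = 20$.
- ND2 and other proprietary microscope formats are not read; convert to
  8-bit PNG/TIFF first.
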