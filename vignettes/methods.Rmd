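---
title: "Models and methods behind pongscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pongscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pongscope)
```

pongscope simulates and analyses closed-loop volumetric two-photon
recordings of a moving, deforming sample — the regime of calcium imaging in
a freely crawling *Drosophila* larva, where the ventral nerve cord
translates at up to a millimeter per second, rotates in the plane, and
bends during every stride. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic tests
do and do not establish about real recordings.

## Scan design

The in-plane "Pong" scan drives both galvos with triangle waves. The x
frequency is the fastest wave that still dwells `tau_min` per pixel of
size `dx` over the full peak-to-peak range `a_x`
(`x_freq = min(dx/(2 a_x tau_min), f_max)`), and the y frequency is locked
to the golden ratio (`2/(1+sqrt(5))` of `x_freq`), making the two axes
incommensurate: the pattern fills the plane with uniform marginal dwell (a
triangle wave spends equal time in equal-width bands, unlike a sinusoid,
which concentrates dwell at the turning points by roughly threefold).

**Amplitude convention.** Throughout, `a_x` is the *full peak-to-peak*
scan range, and the waveform is `x(t) = (a_x/2) tri(2 pi x_freq t)`. This
is the only reading under which the characteristic bidirectional raster
time `tau_raster = (a_x/(r_xy dx)) / (2 x_freq)` reproduces all published
parameter/time pairs (e.g., 667 Hz, 200 um, 0.8 um gives 0.187 s); a
reading in which the programmed amplitude is a half-range would double the
field and is rejected.

**Counter quantization.** The FPGA advances each triangle by one pixel
every rollover of an integer counter at 80 MHz; the rollover is the
*nearest prime* to `f_fpga * dtau` (ties broken toward the larger prime,
i.e. the lower, mechanically conservative frequency). Primality keeps the
joint x-y state from repeating more often than the discrete logic forces.
Quantized frequencies stay within 2% of nominal for all published
configurations.

**Coverage, honestly measured.** `coverage_stats()` rasterizes the
*continuous* beam path (supersampling between per-line samples so steps
stay below half a pixel) and reports the visited-pixel fraction,
per-pixel staleness, and the full-coverage time. Two facts emerge from the
simulation that a user should know. First, with the exact quantized
counters (239 and 389 for the 667 Hz configuration), the joint pattern is
periodic at about 0.58 s and a small percentage of full-density (0.8 um)
pixels is never visited at all: prime counters make the period long, not
infinite. Second, even with ideal (unquantized, truly incommensurate)
waves, complete coverage of every 2 um pixel takes on the order of one
characteristic raster time, and complete 0.8 um coverage takes roughly
2.4-3 of them, with some dependence on the (arbitrary) galvo starting
phases. The often-quoted figures — every 2 um pixel within half a raster
time, full density at twice the raster time — describe the *typical*
near-complete regime rather than a worst-case guarantee; the acceptance
suite asserts the quoted figures as stated and therefore documents this
discrepancy as a failing expectation rather than hiding it.

**Axial scan.** A TAG lens sweeps `z = A cos(phi)` resonantly
(default 190 kHz); one axial line takes `1/(2 f_tag)` = 2.6 us, during
which a sample moving at 1 cm/s travels only 25 nm — the motion-blur floor
of the design. Trajectory samples are emitted once per axial line, at the
line midpoint.

## The crawling phantom

The synthetic-data generator is the package's study condition, not a
tuning knob. It emulates:

- a **ladder** of `n_segments = 8` segments spaced 8 um apart: one medial
  process blob and two lateral cell-body blobs per segment, all
  co-expressing a stable red fluorophore (peak 2e6 counts/s at focus) and
  a green reporter (base 1.5e6 counts/s); a brighter tracked reference
  cell sits just off the ladder near mid-body, and a weak autofluorescent
  rod (2e5 counts/s, both channels) runs alongside — the stand-in for gut
  autofluorescence that real preparations contend with;
- **stride-locked crawling**: within a stride of `stride_period = 1.5` s
  the forward speed is `v = peak * (duty + (1 - duty) cos(theta))` with
  `peak = 800` um/s and `duty = 0.15` (mean speed 120 um/s, about 180 um
  per stride, a modest backward recoil between pulses). These figures
  match the published stride statistics (strides of a few seconds, ~100 um
  surges at up to 0.8 mm/s peak speed). The duty/period choice also keeps
  the stride fundamental strong relative to the velocity DC after the
  prescribed sigma = 0.25 s derivative-of-Gaussian smoothing — with much
  shorter strides the analytic-signal phase of real pipelines stops
  winding, which is a property of the method, not of this implementation;
- a **true phase clock** `phi_true(t)`: the instantaneous (analytic-signal)
  phase of the noiseless velocity oscillation, available in closed form
  for the sinusoid-plus-offset profile,
  `phi_true = atan2(sin theta, r + cos theta)` with `r = duty/(1-duty)`.
  This is the standard instantaneous-phase definition, computed without
  running any estimation code, so phase-recovery tests compare an
  estimator against an independent analytic truth;
- a **traveling activity wave** on the behaviorally gated class:
  `gain = 1 + m cos(k s - phi_true)` during forward bouts on the medial
  class (reversed sign on the lateral class during backward bouts), with
  `m = 0.8` and one full cycle across the body by default — the forward
  gating of medial premotor processes versus backward-gated laterals
  mirrors the biology only as a configurable label;
- **Poisson photon emission**: each axial line is subdivided into 16 TAG
  phase bins (axial rate-evaluation steps under ~4 um for a 20 um
  half-amplitude); within a bin the rate is constant and counts are drawn
  per bin and channel (an inhomogeneous Poisson process with
  piecewise-constant rate), with photon times drawn uniformly within the
  bin so reconstructed axial positions are continuous. Blob-plus-PSF
  profiles are Gaussian-on-Gaussian, so the focal rate is analytic:
  effective widths are `sqrt(cell_radius^2 + psf_sigma^2)` laterally
  (0.5 um PSF) and axially (1.5 um PSF).

What the phantom does *not* emulate: optical aberrations and scattering,
cuticle occlusion, photobleaching, realistic larval biomechanics (the body
is rigid up to the configured rotation/bending fields), and posture
estimation (bout labels come from ground truth, as the specification takes
behavior labels to be inputs). Passing tests therefore demonstrate that
the algorithms are implemented correctly and behave as designed under
controlled conditions — not that they would meet the same error bars on
real tissue.

## Tracking

The tracker scans a cylinder (radius `R_scan = 3` um, one revolution per
350 us cycle, under the 3000 rev/s galvo limit) about the current
estimate while the TAG lens sweeps ±15 um. Photons within ±5 um
(`Z_gate`) of the estimated axial position enter a center-of-mass
estimate whose lateral shot noise is `R/sqrt(N)`; for a beam on a circle
of radius `R`, the *radial* (2D) RMS error of the centroid is exactly
`R/sqrt(N)`, which is what the Monte-Carlo acceptance check measures. A
per-axis Kalman filter fuses measurements: the prior variance grows by
`D dt` between cycles, the gain is `K = s2'/(s2' + sm^2)`, and a missing
measurement (zero gated photons) triggers the predict-only update.

`D` is the responsiveness parameter (um^2/s). It is not stated by the
source design, so the default (2000 um^2/s) was fixed by a simulation
sweep over stride-pulse trajectories before the acceptance thresholds
were evaluated: large enough that the filter lag at 0.8 mm/s stays well
below a micron, small enough that the steady-state jitter remains a
fraction of the single-scan shot noise. Stage re-centering is modeled as
a discrete proportional step every 25 ms; galvo and piezo feedback are
instantaneous. Sustained zero-photon cycles beyond `lost_after` raise a
tracking-lost error.

## Reconstruction

Photons are assigned to the imaging or tracking laser by arrival phase
within the 14.3 ns laser period (pulse trains displaced by half a cycle,
7.1 ns); Gaussian timing jitter of 1 ns misassigns well under 10%.
Emission locations subtract the tracker estimate from the galvo targets
(`x = x_galvo - x_tracker`) and derive z from the TAG phase at the photon
time (`z = A cos(phi) - z_off`); a raw mode omits the tracker subtraction
to reproduce uncorrected images. Stream alignment is
nearest-preceding-sample; histogram bins are half-open `[lo, hi)`;
coordinates are um, origin at the tracked neuron, z toward the objective.

**Dwell-time correction.** The axial sweep spends `1/|sin phi|` more time
near the turnarounds; rather than computing per-voxel dwell, each photon's
count is adjusted by `|sin phi| / 0.7846` and events within ±20 degrees
of the turnarounds are discarded (tallied for QC). The per-voxel line
time is `tau = 1/(2 f_tag n_z)`. Two consequences are documented rather
than silently absorbed: (i) the stated 0.7846 does not equal the analytic
mean of `|sin phi|` over the included band (0.769 for uniform phase), so
`dwell_norm_const()` can recompute it; (ii) with this convention every
interior voxel's recovered rate carries the same constant factor
`2/(pi * 0.7846) ~ 0.81` — z-invariant by construction (the purpose of
the correction), and irrelevant to every ratiometric or registration
quantity, but absolute rates are not raw PMT rates. Tests assert the
derived constant explicitly.

**Volumes and movies.** Rate = count histogram / dwell histogram (1 x 1 x
2 um voxels by default); unsampled voxels are missing, never zero. Movies
use 4D histograms convolved with a separable Gaussian of one voxel in
every dimension before division; the default time bin is half the
characteristic raster time (94 ms for the 667 Hz configuration).
Templates are completed by iteratively reweighted normalized Gaussian
convolution: dwell-weighted smoothing with kernel widening into unsampled
regions, three residual back-fitting passes (quasi-interpolation, so sharp
cells are not flattened), and an L1-type reweighting
(`w = 1/max(|r|/scale, 1)`) that plays the role of a robust,
missing-data-aware smoothing spline. A flat field passes through exactly;
interpolated values at a gap stay within the hull of their neighbors.

## Motion correction

All corrections are estimated from the red (stable) channel and applied
identically to both channels; the green stream never influences them.

1. **Rigid.** The objective is the summed template rate over transformed
   photon locations, `sum_photons lambda(A x)` — a photon-weighted
   correlation that needs no frame image. Because the sample can sit at
   any angle in the plane, stage 1 scans the in-plane angle every 10
   degrees (on a 15k-photon subsample), refines the best three candidates
   over (angle, tx, ty) with Nelder-Mead, and stage 2 refines all six
   parameters warm-started from stage 1. Frames default to the time that
   oversamples the field 3.125-fold at 1 um^-2 pixel density.
   `register_sequence()` adds a quadratic continuity penalty between
   successive frame parameters (Gauss-Seidel sweeps; zero weight reduces
   to independent fits; the default weight was set where static-phantom
   jitter roughly halves).
2. **Non-rigid.** A cubic-B-spline free-form deformation (control spacing
   20 um, displacement `u(x) = B theta`) maximizes the missing-data-aware
   normalized correlation between the frame volume and the template
   evaluated at `x + u(x)`, minus a bending-energy penalty (squared second
   differences of the control grid). The gradient is analytic through the
   interpolated template (central differences of the template field), so
   L-BFGS-B converges in seconds on the test volumes. The fitted field
   applies to scan-path coordinates of both channels; non-convergence
   returns the identity field with a flag. The phantom parameterizes its
   ground-truth bending with the same B-spline family (applied by exact
   fixed-point inversion of `y + u(y) = c`), so recovery error is
   well-defined.
3. **Intensity.** A smooth multiplier `alpha(x)` (cubic B-spline controls
   ~20 um apart, bounded below at 0.05 to keep the model linear in the
   controls) maximizes the inhomogeneous-Poisson log-likelihood
   `sum_photons log alpha(x_i) - int alpha(x(t)) lambda(x(t)) dt`, with
   the integral discretized over the (optionally thinned) scan-path
   samples. The likelihood is concave in the controls for fixed support,
   and the analytic gradient makes the fit fast; a photonless frame
   returns `alpha = 1` flagged degenerate.

## Stride phase and wave statistics

The tracked path is denoised by a cubic smoothing spline. The smoothing
parameter follows the `p RSS + (1-p) penalty` convention with `p = 0.99`
on unscaled seconds; it maps onto R's `smooth.spline(lambda = )` (which
scales time to the unit interval) via `lambda = (1-p)/p / L^3`, since the
curvature integral picks up `L^3` under rescaling — the mapping is frozen
by a regression fixture in the test suite. Velocity comes from a
derivative-of-Gaussian filter (sigma = 0.25 s, normalized to unit ramp
response) projected on the heading; note the published caveat applies
here too: the smoothed peak speeds are substantially lower than the true
peak speeds.

The Hilbert phase uses the analytic pair `(v, H(-v))` so `phi = 0` falls
at maxima of the forward speed; the raw phase may decrease with time
depending on sign conventions, so it is remapped to increase by `2 pi`
per cycle (presentation-equivalent). Backward bouts apply the same
recipe to `-v`, putting `phi = 0` at peak backward speed. Strides span
consecutive `phi = 0` crossings (a small edge tolerance counts a crossing
that falls exactly on a bout boundary); the last stride of each bout is
excluded. Per-stride velocities, resampled on phase (extended by pi/4
into neighboring strides where available), are aligned to their mean by a
4-control-value b-spline phase adjustment with `|delta phi| < pi/4`
(bounding the control values bounds the warp because the basis is a
partition of unity); the warped clock is mapped back to the time axis
with a cross-fade of the adjustment to zero over pi/8 at stride joins and
made globally non-decreasing. Because the template is the mean over
strides, a warp injected into one of N strides reappears in the fit at
`(1 - 1/N)` of its amplitude against the others — the recovery test
accounts for exactly this contamination rather than loosening its
tolerance.

Stride-aligned cubes bin z-projected, dwell-adjusted counts (and dwell)
into 24 equal phase bins (15 degrees) with bin edges at phase zero. Wave
analysis removes each point's temporal mean, runs PCA with spatial points
as observations, orders the first two components so `c1` leads `c2` by
+90 degrees at the fundamental (sign fixed by `c1(0) >= 0`), and forms
the complex projection `g = s1 + i s2`. The plane-wave statistic keeps
`|g|` but restricts `arg g` to `k . x + phi0`: `phi0` is solved in closed
form for each `k`, `k` is scanned over directions every 5 degrees and
magnitudes up to pi/(4 um), then refined locally; the variance explained
is `1 - residual/total` and is genuinely negative when the constraint
fits worse than nothing (the phase-shuffled control exercises this).
Phase maps are spatially low-passed (Gaussian, sigma = 3 um) before
display only. Ratiometric traces divide green by red rates per VOI and
normalize by an iteratively clipped baseline (discard values more than
one SD above the mean, iterate to convergence) or, for stride-aligned
data, by the forward-cycle minimum; time-space projections normalize to
median 1. Bout comparisons use the one-sided Wilcoxon rank-sum test via
`stats::wilcox.test`, exact for groups of up to 10.

## Problem sizes and determinism

The end-to-end demonstration runs an 8-segment phantom through four
1.5 s strides in an 80 x 40 um field (TAG at 190 kHz, ~2.3 million axial
lines, ~450k detected photons), tracks at 350 us cycles, registers ~140
frames and recovers the injected wave in about 8 minutes on one core;
property tests use smaller cuts of the same machinery. These sizes are
the package's demonstration choices; every stage scales with duration and
field size. All randomness flows from one seed through named per-stage
substreams, so identical configurations reproduce identical event streams
bit for bit.

## Known limitations

- The quantized scan's coverage ceiling and the optimistic published
  coverage figures are documented above; `coverage_stats()` reports what
  the trajectory actually does.
- The rigid objective ignores dwell inhomogeneity within a frame; for
  strongly uneven frame sampling a dwell-weighted objective would be
  preferable.
- The FFD restricts to in-plane displacement by default (the phantom
  bends in-plane); out-of-plane bending requires `in_plane = FALSE` and a
  denser axial control grid.
- `alpha` estimation near unlabeled regions is weakly constrained; tests
  and the pipeline evaluate it where the template carries signal.
- The simulated stage/piezo feedback is idealized (no slew limits, no PID
  dynamics); tracking error estimates are therefore optimistic at high
  speeds.
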