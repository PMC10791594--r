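---
title: "Surrogate-driven motion models for cone-beam CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-driven motion models for cone-beam CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A one-minute 3D cone-beam CT (CBCT) scan of the thorax acquires a few hundred
2D projections while the patient breathes. Reconstructing them as if the
anatomy were static blurs the tumor and diaphragm; sorting the projections
into respiratory phases (4DCBCT) trades that blur for severe view-aliasing
streaks and assumes periodic breathing. `cbctmoco` takes the third route: it
estimates the *motion at every projection* together with a single motion-free
volume, directly from the unsorted projections of a standard scan.

## The model

Let $P_t$ be the measured projection at time $t$, $A_t$ the cone-beam forward
projection at the frame's gantry angle, and $I_0$ the motion-free reference
image. The frame image is a warp of the reference,
$I_t(x) = I_0(x + D_t(x))$ (a pull-back resampling), with the dense
displacement field $D_t$ generated by a cubic B-spline free-form deformation
(FFD): $D_t = \phi(M_t)$, where $M_t$ holds 3-vector displacements on a
coarse control-point grid. The *correspondence model* ties the per-frame
control points linearly to $N_s = 2$ respiratory surrogate signals,

$$M_t = \sum_{i=1}^{N_s} S_{it}\, C_i ,$$

so the entire motion trajectory is parameterised by two static component
fields $C_1, C_2$ plus two measured 1-D signals. Two signals (a respiratory
amplitude and, for the extracted-signal variant, its temporal derivative as a
breathing-rate proxy) suffice to represent intra- and inter-cycle variation
including hysteresis; more components invite overfitting.

The parameters minimise a projection-domain loss,

$$f(C) = -\sum_t L\!\left(P_t,\; A_t\, T(I_0, \phi(S_t C))\right),$$

where $L$ is the *localized normalized cross-correlation* (LNCC): the mean
over valid detector pixels of a Gaussian-windowed correlation coefficient.
LNCC is invariant to locally affine intensity relationships, which is what
makes the method transferable to real scanners where scatter and beam
hardening shift intensities between measured and simulated projections;
sum-of-squares similarity would fail there.

The gradient is assembled analytically by the chain rule: the LNCC gradient
with respect to the estimated projection is backprojected by the exact
adjoint $A_t^{*}$ of the forward projector, multiplied voxel-wise by the
spatial gradient of $I_0$ at the warped sample positions, pushed through the
FFD transpose onto the control points, and weighted by $S_{it}$ into
component $i$. Every factor in this chain has a paired adjoint in the
package, and the full assembled gradient is validated against central finite
differences of the loss (a dedicated acceptance test checks every component
of a small instance at $10^{-3}$ relative).

Because $I_0$ is itself unknown, fitting alternates with *motion-compensated
FDK* (MC-FDK): each frame's cosine-weighted, ramp-filtered, distance-weighted
backprojection volume is resampled into the reference frame through the
numerically inverted $D_t$ before accumulation. With zero motion MC-FDK is
bit-near identical to plain FDK by construction (same accumulation loop).

## The optimisation schedule

Per resolution level (1/4 then 1/2 of the original resolution):

1. pool projections to the level (block average), build the level grid;
2. initialise $I_0$ by standard FDK (first level) or by MC-FDK with the
   refined model (second level; the components advance by exact dyadic
   B-spline subdivision);
3. alternate up to 6 times: (a) up to 100 stochastic gradient steps on
   evenly-spaced projection subsets (one tenth of the frames each, visiting
   order shuffled by the seeded RNG), (b) one MC-FDK update of $I_0$.

Control points sit every 8 voxels of the level image. Fitting at full
resolution is deliberately omitted — it multiplies runtime for little
accuracy, since the deformation is already parameterised coarsely.

### Step size and stability at desk scale

At full clinical scale (375 mm of anatomy at 1 mm, sub-millimetre detector
pixels, 310 views) this loss is well-conditioned. The package's validation runs
at a deliberately reduced scale (64³ voxels at 4 mm, 60 views), and three
interacting degeneracies surfaced there that informed the defaults:

* **Bandwidth mismatch.** The model-side projections come from the coarse
  level image and are blurrier than block-averaged measurements. LNCC is not
  blur-invariant: the optimiser is rewarded for "sharpening" deformations
  that grow without bound and bias the recovered amplitude. The measured
  level projections are therefore Gaussian band-limited by
  `level_blur_px = 0.5` level pixels, matching the two bandwidths.
* **Streak chasing.** A 60-view FDK image carries view-aliasing streaks whose
  spacing matches a level-scaled LNCC window, so the fit warped streaks
  instead of anatomy. The window is therefore kept at `sigma_px = 5` pixels
  *of the current level* rather than scaled down with resolution — wide
  enough to average over streak texture, local enough to keep the affine
  invariance useful.
* **Step schedule.** The first gradient step is sized by backtracking (start
  at a `step_scale = 0.15` level-voxel node displacement, halve until the
  subset loss decreases) and then decays as $1/(1 + t/\tau k)$ over the
  level's iterations ($\tau$ = `step_decay_epochs` = 1 epoch, $k$ = subsets
  per epoch). A constant step — adequate at full scale — random-walks
  along near-null directions of the desk-scale loss.

These are defaults, not hard-wired behaviour; `fit_config()` exposes all
three.

## Numerical choices

* **Projector pair.** Ray-driven trilinear sampling with a step of half the
  smallest voxel spacing; the backprojector is the *exact transpose* of the
  same sampling loop (adjointness holds to ~1e-16, an explicit acceptance
  contract). FDK uses a separate voxel-driven distance-weighted
  backprojector, a Ram-Lak kernel apodised with a Hann window, and the
  $2\pi/N_t$ angular weight; a simulated homogeneous sphere reconstructs to
  its true attenuation within a few tenths of a percent.
* **Interpolation in the loss.** The public `warp_image()` defaults to
  trilinear resampling, but the fitting loss warps $I_0$ with cubic B-spline
  interpolation (prefiltered, mirror boundary). A trilinear warp has
  piecewise-constant intensity derivatives — discontinuous across voxel
  faces and one-sided exactly at grid nodes — which cannot satisfy a
  finite-difference gradient contract at $10^{-3}$; the cubic interpolant
  makes the loss $C^1$ in the displacements. Near the grid boundary the
  spline is evaluated with mirror-extended coefficients so interpolation
  stays exact at every voxel and the loss remains continuous (a hard
  stencil-validity cutoff provably breaks both).
* **Intensity gradients.** In cubic mode the analytic spline derivative; in
  linear mode a half-voxel secant of the trilinear interpolant, which
  reduces exactly to central differences at zero displacement.
* **FOV handling.** Voxels outside the inscribed reconstruction cylinder are
  null (`NA`) and contribute zero to projections; detector pixels whose rays
  leave the cylinder while inside the grid (checked exactly via the convex
  radial profile along the ray, with a one-voxel margin) are excluded from
  the loss. Losses average (not sum) over valid pixels so FOV masking does
  not bias frames.
* **LNCC floor.** Local variances and covariance are floored by
  $10^{-8} \times \mathrm{range}(P)^2$; the floor also enters the covariance
  numerator so identical (even locally flat) images score exactly 1 and
  $|L| \le 1$ still holds. The floor is tied to the measured image only,
  keeping the loss smooth in the estimated image; exchange symmetry of the
  value therefore holds to O(floor).
* **DVF inversion.** MC-FDK needs reference-to-frame mappings; the stored
  frame-to-reference fields are inverted by fixed-point iteration (at most
  20 sweeps, stop at a mean update below 0.01 voxel).
* **No deformation regularisation by default.** The correspondence model's
  coarse node spacing plus the bandwidth-matching above proved sufficient on
  the validation conditions; a bending-energy term was considered and
  rejected because the ground-truth fields vary on the scale of one node
  spacing and would be penalised alongside the failure modes.
* **Degenerate inputs.** Empty projection stacks, geometry/grid mismatches,
  missing surrogate rows, constant traces and insufficient control-grid
  coverage raise immediate errors; a non-finite loss aborts the fit with the
  level/iteration in the message.

## The synthetic study and what it does (not) show

The phantom emulates the essential features of a digital-thorax simulation:
an ellipsoidal body (0.02/mm, approximately water), two lungs (0.005/mm), a
denser spine rod, and a 15 mm-radius spherical tumor in the lower left lung;
375×375×343 at 1 mm is available, with 128³ at 2 mm as the default and 64³
at 4 mm used in the validation runs. Projections follow an Elekta-style
geometry (SID 1000 mm, SDD 1536 mm, 360°; 310 views at 5.4 fps for a
one-minute scan). The reduced recovery experiment uses 60 views *uniformly
spanning the same one-minute rotation* — a temporally subsampled standard
protocol, as in public challenge datasets — because surrogate extraction
needs a record several times longer than the 10-second separation between
breathing and gantry-rotation frequencies.

Breathing traces use the classic $\cos^4$ respiratory waveform (period 4 s).
The *regular* regime drives diaphragm and chest in phase with fixed
amplitude; the *irregular* regime offsets the chest by a quarter cycle
(hysteresis) and draws per-cycle amplitudes from a seeded ±30% range.
Peak-to-peak defaults are 30 mm (diaphragm, superior-inferior) and 7 mm
(chest, anterior-posterior) — deep but clinically plausible breathing,
chosen so the uncorrected tumor excursion lands in the range reported for
uncorrected scenarios in published simulations of this kind. Ground-truth
motion is built, by default, *inside the model class*: a fixed ground-truth
correspondence model with a superior-inferior component peaking at the
diaphragm and an anterior-posterior component peaking at the chest wall,
driven by the normalized traces, with amplitudes bounded so the Jacobian
stays positive (deformations invertible). This guarantees the fit problem
has an exact solution, which is precisely what a recovery experiment should
test; an "analytic" mechanism with dense smooth fields is available for
out-of-class checks.

What the synthetic study does **not** emulate: sliding motion at the
chest-wall/lung interface (the B-spline FFD cannot represent discontinuities
anyway), anatomical texture, scatter, beam hardening, detector lag and
noise, and truncated fields of view. Passing the recovery tests therefore
demonstrates the correctness and conditioning of the estimation machinery,
not clinical performance.

Validation problem sizes were chosen as the smallest instances that leave
the phenomena intact: 16³ grids for operator identities and the
finite-difference gradient audit; 64³/60 views for recovery, the static-scan
null test and the MC-FDK identity; 48³/310 views for surrogate extraction
(a short record cannot separate a 0.1 Hz trend from breathing, so extraction
is tested on full one-minute scans). One caveat found during development and
worth keeping in mind when changing scales: the detector sampling must keep
breathing motion at two or more detector pixels at the finest fitting level,
otherwise the pooled projections cannot see the motion at all.

## Surrogate extraction

The intensity-analysis signal is the per-frame sum of projection pixel
values, split into a low-frequency part (gantry rotation — the body is not
rotationally symmetric) and a high-frequency part (respiration) by a
zero-phase 2nd-order Butterworth high-pass at 0.1 Hz — below normal
breathing (~0.2–0.5 Hz), above the rotation rate (~1/60 Hz). The record is
point-reflected at both ends before filtering; without padding the filter's
edge transients leak the gantry trend back into the signal. The second
signal is the temporal gradient of the first (central differences, 3-sample
moving average). Both are normalized to mean 0, sample standard deviation 1.
The physical origin of the signal in this simulation is the non-volume-
preserving part of the deformation sweeping tissue (diaphragm dome, chest
wall) through the cone's depth-weighted sensitivity profile; its sign is
absorbed by the linear correspondence model.

## Known limitations

* Truncated projections (anatomy outside the FOV at some angles) are not
  handled; the mismatch they cause is a structural limitation of fitting
  line integrals of a finite reconstruction.
* On *motion-free* data under heavy angular subsampling (60 views) with
  detector sampling much finer than the reconstruction grid, the fit can
  hallucinate up to ~0.5 voxel of motion by warping view-aliasing texture;
  under the standard 310-view protocol the estimated motion on static data
  is numerically zero. The static-scan null test runs under the standard
  protocol.
* The recovered motion amplitude at desk scale retains a small negative bias
  (~10–15%), the residual of the bandwidth compromise described above.
* Offset detectors, short-scan weighting and iterative reconstruction are
  out of scope.
* The per-frame estimate for frames whose surrogate values are far outside
  the fitted range is an extrapolation of the linear model.
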