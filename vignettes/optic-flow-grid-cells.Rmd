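---
title: "From optic flow to grid-cell firing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From optic flow to grid-cell firing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowgrid)
```

## The question the model asks

Grid cells in the rat entorhinal cortex fire on the vertices of a hexagonal
lattice covering the environment. Their firing is usually explained by path
integration of a self-motion signal, with the vestibular and sensorimotor
systems as the presumed velocity sources. `flowgrid` implements a complete
model of an alternative: can *optic flow alone* — the pattern of visual
motion on the retina, corrupted by sensing noise — supply a velocity signal
accurate enough to drive a grid-cell mechanism?

The model is a chain of six stages, each exposed as its own module:

1. a foraging **trajectory** on a circular platform (synthetic, or read
   from tracked positions and cleaned);
2. analytic **visual image motion** for a spherical camera moving along
   that trajectory over a textured ground plane;
3. additive Gaussian **flow noise**, standing in for the errors of a
   brightness-based flow estimator;
4. a **template decoder** that recovers linear speed $v_z$ and yaw rate
   $\omega_y$ from each single flow field;
5. forward-Euler **path integration** of the decoded velocities, with an
   optional periodic reset to ground truth standing in for non-visual
   cues; and
6. a velocity-controlled **oscillatory-interference** grid-cell model plus
   **scoring** (rate maps, spatial autocorrelograms, gridness, spacing).

## Camera model and flow equations

The sensor is a spherical camera: pixel positions are azimuth/elevation
pairs $(\theta, \phi)$ on a regular $40 \times 20$ lattice spanning
$\pm 120^\circ \times \pm 60^\circ$ (800 pixels, $6^\circ$ spacing). The
camera frame is left-handed (z forward, y up, x right); the nodal point
sits $h = 3.5$ cm above the ground and the optical axis may be tilted by
$\gamma$ (positive = downward). Angular image velocity decomposes into a
translational part that scales with inverse depth and a depth-free
rotational part; both are implemented exactly (`image_motion_full()`), and
the planar special case used throughout
(`image_motion_curvilinear()`) restricts the self-motion to
$(v_z, \omega_y)$, speed parallel to the ground plus yaw about the ground
normal.

Depth comes from the ground plane: $D = h / s$ with
$s = \sin\gamma\cos\theta\cos\phi - \cos\gamma\sin\phi$ the inner product
of the pixel ray with the downward ground normal expressed in the camera
frame. The platform is intersected analytically as a disc of radius 100 cm
(the recorded cage radius of 85 cm plus a 15 cm annulus, so a camera at
the cage boundary looking outward still receives textured ground). Rays
with $s \le 0$, beyond the disc, or beyond $D_{max} = 1000$ cm are masked
invalid and excluded from every downstream sum. We intersect an exact
disc rather than a triangulated approximation of it; the triangle count of
a renderer mesh is a rendering artifact, not part of the model.

Two identities are enforced by tests at machine precision: translational
and rotational flow superpose linearly, and multiplying speed and depth by
a common factor leaves the flow unchanged. The latter invariance is why a
monocular observer cannot know its speed without a depth anchor — here,
the known eye height above a ground plane.

## Units

All flow fields are angular rates in degrees per second. The flow-noise
level `sigma_flow` is one independent zero-mean Gaussian draw per pixel
component per frame (50 Hz), on the same scale as the flow field, with the
sweep values 0–50 used in the experiments. The tuning widths of the
template objectives are likewise taken at their tabulated face values,
$\sigma_v = 10$ and $\sigma_\omega = 25$, applied to the matching
residuals in these native units (the linear residual additionally carries
the eye height, in cm). This is the one internally consistent reading we
found that keeps the published position-error and grid-score magnitudes
reachable: a per-frame noise draw interpreted as a *rate* noise of
$50\times$ that size would, by a simple information-bound argument
(per-frame yaw error cannot fall below pixel noise divided by
$\sqrt{n}$), force a heading random walk two orders of magnitude larger
than the published errors. Both widths remain configuration knobs on
`template_bank()`.

## Template decoding

The decoder never solves an inverse problem; it compares the sensed flow
field against precomputed templates, in the spirit of biological
template models of heading perception. The constrained flow model is
$\dot\psi = \frac{1}{h}\,\vec a\, v_z + \vec b\,\omega_y$ per pixel, with
$\vec a$ folding the plane constraint into the translational field and
$\vec b$ the rotational field. Two one-dimensional searches replace the
quadratic joint search:

* **Linear stage.** Projecting the flow on $\vec b^\perp$ (the pixelwise
  90° rotation of $\vec b$) annihilates the rotational component exactly,
  whatever $\omega_y$ is. The residual against each sampled speed
  $v_j \in \{2, 2.5, \ldots, 60\}$ cm/s (117 templates) is scored with a
  Gaussian tuning curve and averaged over valid pixels.
* **Rotational stage.** With $\hat v$ fixed, the residual against each
  sampled $\omega_k \in \{-4500, \ldots, 4500\}$ deg/s in 20 deg/s steps
  (451 templates) is scored the same way.

A test verifies this two-stage scheme lands within one grid step of the
brute-force joint search over all $117 \times 451$ combinations with a
Euclidean objective.

The profile readout is a *local vector sum*: the match-weighted mean of
the axis restricted to 2 % of the samples centred on the peak (half-width
at least one sample, clipped at the ends). It interpolates between the
discrete templates — making noise-free decoding of on-grid velocities
exact and off-grid velocities nearly so — without the boundary bias a
global vector sum has when the profile does not decay to zero at the axis
ends. Ties at the peak resolve to the lowest index.

The per-frame loop over a whole trajectory (mask, flow, noise, two
matches, readout) runs in compiled code; Gaussian terms whose exponent
exceeds 30 (about $10^{-13}$ of a peak contribution) are skipped. A
pure-R reference path computes the same quantities one frame at a time
and the two are tested for exact agreement at zero noise.

## Path integration and reset

Heading is the integral of $\hat\omega_y$; position advances by
$\hat v_z\,(\cos\phi, \sin\phi)\,dt$ at each 20 ms step, position first
and heading second, so that integrating the velocities *derived from* a
trajectory reproduces that trajectory to floating-point accuracy (tested
to $10^{-3}$ cm over 54,000 steps). The reset mechanism replaces position
*and* orientation with ground truth every $T_{reset}$ minutes and lets
integration continue — an abstraction of landmark/vestibular corrections,
not a model of them.

Error is reported as the per-sample Euclidean distance, and an angle
error defined (the published definition being ambiguous) as the absolute
wrapped difference between the *bearings* of true and estimated position
seen from the arena centre; a heading-difference alternative is available
via `position_error_stats(..., angle = "heading")`.

Why does a white per-frame yaw error not destroy the integral? The
decoded errors are independent across frames, so heading performs a slow
random walk; but because the animal itself turns continuously, the
direction in which a heading error displaces the integrated position also
rotates, and the position error grows diffusively rather than
ballistically. This is the property that makes purely visual path
integration workable at all over tens of minutes.

## Oscillatory interference and scoring

Each of three dendritic oscillations (basis directions 0°, 120°, 240°)
advances its phase by $\omega\beta$ times the displacement of the
integrated path along its basis vector; a spike occurs when the product
of the three somatic+dendritic interference pairs exceeds
$\Theta = 1.8$. The closed forms $L = 1/(\beta f)$ (band spacing) and
$G = 2/(\sqrt3\,\beta f)$ (grid spacing) follow from the envelope
frequencies; with $f = 7.38$ Hz and $\beta = 0.00385$ s/cm,
$G \approx 41$ cm. The displacement integral is computed as
$(p(t) - p(0)) \cdot \vec b_k$, which is exactly the cumulative velocity
projection (tested against the explicit cumulative sum); spikes are
evaluated at the 50 Hz trajectory rate (about 6.8 samples per theta
cycle), with an optional oversampling factor since no oscillator time
step is prescribed by the theory. Initial dendritic phases are zero. Note
that along a basis axis the three-way product's envelope vanishes at odd
multiples of $L$: vertices on that axis recur every $2L$, while the
nearest off-axis vertices sit at distance $G = 2L/\sqrt3$ — the measured
quantity in everything below is $G$.

Spikes are *registered at the true positions* while the oscillator is
*driven by the integrated (possibly reset) path*: integration error thus
deforms the spatial firing pattern exactly as it would in an experiment
where the tracker reports the true position.

Scoring follows the standard rate-map pipeline: spike counts and
occupancy time binned on a $201 \times 201$ lattice over the arena, both
convolved with a $9 \times 9$ Gaussian kernel ($\sigma = 2$ px) before
division; never-visited bins are `NA`, not zero. The spatial
autocorrelogram is the Pearson correlation at every 2-D lag over
pairwise-complete visited bins (FFT-accelerated, minimum 20 overlapping
bins). The gridness score is
$\min(r_{60}, r_{120}) - \max(r_{30}, r_{90}, r_{150})$ over an annulus;
we take the maximum over a small family of annuli derived from the
detected central-peak radius and six-peak ring — the expanding-annulus
convention of the developmental grid-cell literature — because any single
fixed annulus dilutes the rotation correlations with featureless
surround. Grid spacing is estimated independently of the autocorrelogram
by k-means clustering of spike positions (10 restarts, k = number of
detected fields) and averaging centre distances within 1.3× the minimum
centre distance; centroids much closer than the typical nearest-neighbour
distance (under 0.4× the median) are first merged, since a split field
would otherwise corrupt the minimum-distance criterion.

Field detection excludes bins whose smoothed occupancy is below 20 % of
the mean visited-bin occupancy: a bin crossed once during a spike reports
a rate of one spike per sample period (50 Hz) no matter what the cell
does, and such artefacts would otherwise define the map peak.

## The synthetic trajectory generator

The generator emulates the movement statistics of a foraging rat rather
than any specific recording: 50 Hz sampling inside an 85 cm radius; speed
follows a latent AR(1) process mapped onto a Gamma(3, scale 5) marginal —
mode 10 cm/s, mean 15 cm/s, a right tail reaching toward 50–60 cm/s —
clipped to [2.5, 60] cm/s; heading turns by an AR(1) turning-rate process
(stationary sd 40 deg/s, lag-1 0.97 at 50 Hz) capped at 80° per step; and
within 10 cm of the boundary a progressive inward turn bias keeps the
animal inside. These choices make the output a fixpoint of the cleaning
rules and give near-complete arena coverage in an 18-minute session
(tested: ≥ 90 % of 10 cm bins), which the grid-score analyses require.
What it does *not* emulate: head movements decoupled from body motion,
tracking jitter, thigmotaxis (real rats over-sample the wall zone), and
pauses below 2.5 cm/s — so tests passing on synthetic data show the
pipeline's properties under idealised body motion, not robustness to
tracker artefacts; the cleaning rules exist for the latter and are tested
on constructed jitter.

## Numerical and design choices

* Cleaning applies its three rules per pass (turn-insertion, slow-removal,
  fast-insertion, each front to back) to a fixpoint with a 10-pass cap and
  a warning if still firing. Midpoint insertion cannot reduce a turn angle
  between unchanged neighbours by itself; sharp turns are in practice
  eliminated through the interplay with slow-point removal, which is how
  tracking jitter (sub-threshold steps) actually presents. A geometric
  corner with long segments therefore hits the cap — such input is not
  trajectory jitter and the warning says so.
* Timestamps are regularised to exactly 1/50 s after cleaning; inserted
  points take the midpoint position.
* Heading at sample $i$ is the direction of segment $i \to i+1$ (tangent
  assumption); the last sample inherits its predecessor's heading.
* The reset period is counted in samples ($60 \cdot 50 \cdot T_{reset}$);
  resets land on exact sample multiples.
* `subsample_templates()` splits a total budget proportionally to the
  default axis sizes (117:451) and thins each axis evenly, keeping the
  end points; uneven thinned axes fall back to full-profile evaluation in
  the compiled path.
* Problem sizes in the test suite: module tests run seconds-long
  trajectories; the end-to-end checks use one 9-minute noise-free run,
  three 9-minute noisy runs, and three 18-minute scored runs — the sizes
  at which the measured quantities are already stable.

## Known limitations

* With invalid-depth pixels excluded from all sums (the implemented
  rule), upward tilt discards up to half the sensor and rotational
  decoding degrades asymmetrically in the tilt angle; keeping sky pixels
  in the rotational stage (whose flow component is depth-free) would
  restore the symmetry at the cost of a second validity notion. The
  exclusion rule was kept for uniformity.
* The gridness score depends on the annulus convention; the
  expanding-annulus maximum reported here is systematically higher than a
  single fixed annulus around the six-peak ring (by roughly 0.3–0.6 on
  hexagonal maps).
* Bearing-based angle error is ill-conditioned when the animal is near
  the arena centre; with position errors of a few cm the mean is still
  well behaved, but for large integration errors the heading-based
  definition is the more interpretable one.
* No eye or head movements, no walls, no landmark model: the reset is the
  only non-flow channel, by design.

## A worked example

```{r example, eval = FALSE}
library(flowgrid)
run <- run_pipeline(duration = 1080, seed = 7, sigma_flow = 12.5,
                    t_reset = 1)
print(run)
plot(run)
```

An 18-minute run at moderate noise with a 1-minute reset takes about half
a minute on one core and reports sub-centimetre mean position error, a
gridness score near 1.9, and a measured spacing within a few percent of
the theoretical 40.6 cm.
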