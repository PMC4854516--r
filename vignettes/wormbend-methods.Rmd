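---
title: "Quantifying head bending and propulsion efficiency in undulating worms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying head bending and propulsion efficiency in undulating worms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormbend)
```

## What this package computes

A freely moving *C. elegans* propels itself with a dorsoventral bending wave
that travels from head to tail at roughly 1 Hz. Two families of quantities
summarise this behaviour and its neural control:

* **Head-bending amplitude.** The worm body is represented by a centerline
  divided into 100 segments; signed, body-length-normalised curvature
  (kappa\*L, ventral positive) per segment and frame forms a *curvature
  kymograph*. The head region is the first 18 segments (the anterior 18% of
  the body from the nose tip); *head curvature* is their per-frame mean; and
  the *head-bending amplitude* of a recording is the population standard
  deviation of that trace over time. For a sinusoidal trace of amplitude A
  this converges to A/sqrt(2).

* **Propulsion efficiency and drag anisotropy.** During a bout of forward
  locomotion, the actual centroid speed V_a, the speed V_w of the undulatory
  wave in the worm's frame, and the angle of attack theta_a (the mean
  absolute acute angle between body segments and the direction of motion)
  characterise the gait. Resistive force theory (RFT) for slender bodies in
  viscous media predicts the efficiency eta = V_a/V_w from theta_a through a
  single mechanical parameter, the drag-coefficient ratio K = C_perp/C_par.
  In the small-angle limit,

  eta(theta_a; K) = (K - 1) q / (1 + K q),  q = (pi^2/8) theta_a^2,

  with theta_a in radians. Here q is the mean squared tangent angle of a
  sinusoidal wave whose mean absolute tangent angle equals theta_a
  (mean |sin| = 2/pi maps the two scales). The curve vanishes at theta_a = 0
  and at K = 1: isotropic drag produces no thrust. `fit_drag_ratio()`
  estimates K from a table of (theta_a, efficiency) bouts by unweighted
  least squares and returns a classed model object with the usual
  `print`/`summary`/`coef`/`predict`/`plot`/`simulate`/`residuals` methods.

Calcium imaging of head motor neurons links the two: fluorescence traces are
background-subtracted ROI sums, min-max normalised per recording
((F - F_min)/(F_max - F_min)), and cross-correlated with the bending trace;
the group statistic is the signed maximum-absolute correlation inside a 1 s
window centred on the reference lag T_p of the control group's mean
correlogram.

## Certifying the small-angle curve against a force-balance simulation

The closed-form efficiency curve is an idealisation. `rft_force_balance()`
is an independent numerical oracle: it prescribes periodic centerline
kinematics, applies local anisotropic drag per unit length
(f = -C_par (u.t)t - C_perp (u.n)n), solves the zero-net-force and
zero-net-torque conditions for the instantaneous rigid translation and
rotation, and integrates the rigid motion with a fourth-order Runge-Kutta
scheme over three undulation periods (discarding one transient period).

The closed form assumes an infinitely long wave. A body carrying a single
wavelength loses roughly 40% of its predicted speed to yaw and lateral
recoil; with five wavelengths on the body the loss shrinks to a few
percent. The certification therefore prescribes a five-wavelength,
small-amplitude shape (wavelength 0.2 body lengths, 151 body points, 150
steps per period): the transcribed curve then agrees with the simulation
within 5% relative error for theta_a up to 15 degrees and K in [1.2, 2.0],
and K = 1 yields |V_a| below 1e-6 mm/s (machine-precision zero, because
isotropic drag makes the centroid velocity vanish identically at every
instant). Beyond the small-angle regime the discrepancy grows with
amplitude; the curve should not be extrapolated past theta_a of about 60
degrees, which is where `fit_drag_ratio()` caps the data it uses.

## The synthetic-data generator as the study condition

No raw recordings are publicly deposited, so every stage is validated
against a generator with known ground truth:

* **Bending wave.** kappa\*L(s, t) = A sin(2 pi f t - 2 pi s / lambda) at
  the 100 segment midpoints. Defaults: amplitude A = 4 (giving peak tangent
  angles near 30 degrees, a typical crawling gait), wavelength 0.65 body
  lengths (the classic crawling wavelength), frequency 1 Hz, 5 Hz sampling,
  body length 1 mm. Optional Gaussian curvature noise; every random draw is
  a pure function of the seed.

* **Movies.** Centerlines are integrated from the curvature rows and
  painted as unions of discs with a sqrt-sine tapered half-width profile
  (maximum 0.04 L mid-body, pointed tips). A pure sine taper was rejected
  because its tips thin out so slowly that ~6% of the body length renders as
  empty pixels; the square-root taper keeps the rendered tip within ~0.5% of
  the true tip while preserving the convex-curvature extrema that endpoint
  detection relies on. Frames default to 5 um/px (a 1 mm worm spans ~200
  px), matching typical single-worm tracker optics; at a coarser 10 um/px
  tip curvature becomes unrecoverable. Translation is kinematic (an optional
  rigid drift), not hydrodynamic.

* **Calcium traces.** Ventral- and dorsal-like traces are half-wave
  rectified copies of the (lagged) head curvature plus noise, emulating the
  anti-correlated, bending-locked signals of the dorsal and ventral head
  motor neurons. The rectified-linear coupling is a stand-in for testing
  recovery of lag and sign, not a claim about the underlying biophysics.

* **RFT bouts.** (theta_a, efficiency) pairs drawn from the small-angle
  curve at a known ratio with truncated Gaussian noise; an optional
  wave-speed model V_w(theta_a) lets binned-speed analyses be exercised
  (with V_w declining in theta_a, the binned actual speed V_a = eta V_w
  peaks at an intermediate angle, reproducing the qualitative speed
  optimum near 45 degrees).

What passing these tests does *not* show: robustness to uneven
illumination, motion blur, self-occluding (coiled) postures, or multi-worm
scenes. Coiled frames are dropped and flagged rather than guessed.

## Posture extraction: algorithm and numerical choices

The centerline algorithm is unspecified in the field's standard
descriptions ("extracted and smoothened"), so the package fixes and
documents one:

1. **Binarisation.** Otsu or fixed threshold; largest connected component;
   holes filled (EBImage primitives).
2. **Boundary.** The ordered contour is resampled to uniform arclength and
   lightly smoothed (circular moving average, window 2% of perimeter).
3. **Endpoints.** Head and tail are the two boundary points of maximum
   convex curvature, the second constrained to lie at least a quarter
   perimeter from the first (this rejects pixel stair-step spikes and the
   outer apex of a deep body bend). A near-circular blob fails an
   isoperimetric gate (P^2/4*pi*A < 1.5) before any peak search. Because a
   rounded cap smears the curvature peak along the cap, each endpoint is
   snapped to the geometric apex of its tip: the boundary point farthest
   from the midpoint of its neighbourhood chord, with the centroid of
   near-farthest points giving sub-pixel resolution.
4. **Midline.** Nearest-point correspondences between the two flanks give a
   first midline; three relaxation passes then recentre each point at the
   midpoint of the two boundary intersections of its normal. Moves are
   accepted only when the implied half-width and displacement are plausible
   against the body's median half-width, because normals near the tips graze
   the cap and would otherwise jump off the body.
5. **Trim and smooth.** The degenerate tip neighbourhoods are trimmed; the
   tangent angle (sampled on two-point-span chords, which a single jittered
   point cannot reverse) is fitted with a cubic smoothing spline
   (default 16 equivalent degrees of freedom, chosen on noise-free synthetic
   round trips where the signal amplitude transfer is 99.7%). The spline is
   fitted on a domain padded with local-quadratic extrapolations so its
   natural boundary conditions do not flatten the curvature at the tips.
6. **Rebuild and bridge.** Positions are rebuilt by integrating the
   smoothed tangent angle, with the closure mismatch redistributed linearly
   so both ends stay anchored. Each end is then continued to the detected
   tip apex with a constant-curvature bridge whose heading and turning rate
   come from a local quadratic fit at the junction; the turning rate is
   shrunk by its standard error (an empirical-Bayes step that keeps noise
   on a straight body from bending the bridge). Only the bridge *length*
   uses the apex, so apex pixel noise cannot inject curvature.
7. **Curvature.** kappa_i = d psi / d s by central differences (second-order
   one-sided at the end segments), times the arclength L.

Head/tail identity is automated from wave propagation: the phase of the
dominant temporal frequency, unwrapped across interior segments, has a
negative slope when the wave travels head to tail; the end the phase leads
is the head. The fit's R^2 and the spectral concentration gate ambiguous
recordings, which raise an orientation error prompting manual assignment
(`head_end = "first"`/`"last"`).

Measured performance at the default study gait (noise-free): kymograph
closure RMSE is 4.7% of the ground-truth range (13.4% of its RMS), the
head-bending amplitude transfer is +1.1%, a straight worm's centerline is
collinear within 0.83 px, and per-frame arclength varies by ~0.2%. Across
other gaits (amplitudes 2-6, wavelengths 0.5-0.65) the amplitude transfer
varies within roughly +/-8%: tip extraction errors are a common mode across
the 18 head segments and do not average out, which is the main caveat when
comparing absolute amplitudes across very different gaits. "Normalized
RMSE" here always means RMSE divided by the ground-truth range (max minus
min), the standard normalisation for a signed, zero-mean signal.

## Wave speed, bouts and angles

`wave_speed()` estimates the phase speed of the curvature wave as the
phase-lag slope across interior segments (segments 20-80 of 100, avoiding
tip noise) at the dominant temporal frequency. For a narrowband wave this
phase lag *is* the lag at which pairwise segment cross-correlations peak,
but reading it from the cross-spectrum gives sub-frame resolution: spectral
leakage multiplies every segment's coefficient by the same complex factor,
so phase differences are exact even off the frequency grid. The dominant
frequency itself is refined by parabolic interpolation of the mean
periodogram peak. Incoherent kymographs (low spectral concentration or a
poor phase-line fit) raise a wave-speed error instead of returning a
number.

Bout segmentation keeps maximal runs of forward frames: posture-valid, not
flagged as reversals, and with |mean whole-body kappa\*L| below pi/2 (the
turn-exclusion threshold). The direction of forward movement for the angle
of attack is the unit vector of the bout's net centroid displacement;
per-frame alternatives were rejected because head swings contaminate them.
Angles are unsigned acute angles in [0, 90) degrees, averaged over all
segments and frames, as in the efficiency theory (a trim option restricts
the body range). Efficiency is V_a/V_w by construction, and V_a projects
the net displacement on its own direction, so it cannot exceed the raw
path speed.

`fit_drag_ratio()` minimises the sum of squared efficiency residuals over
K in [1, 20] with `stats::optimize` (tolerance 1e-9; noiseless closures
recover the generator to better than four significant digits). Estimates
at the K = 1 boundary are flagged: they mean no measurable propulsion
anisotropy. Uncertainty comes from a nonparametric bootstrap over bouts
(default 1000 resamples) because the theory provides no analytic standard
error for this nonlinear one-parameter fit.

## Cross-correlation choices

Correlograms are Pearson correlations at every integer-frame lag up to 20 s
(100 frames at 5 Hz), each lag normalised over its own overlap window so
edge lags remain bona fide correlations in [-1, 1]; missing frames are
pairwise-deleted. Because the coefficient is normalisation-invariant, it
does not matter whether traces were min-max scaled or z-scored upstream.
The 1 s peak window is the closed interval [T_p - 0.5, T_p + 0.5] s (five
lags at 5 Hz); ties inside the window break toward the lag nearest T_p,
and ties in the group-mean reference peak (possible for periodic or
mirror-symmetric correlograms) break toward lag zero.

## Problem sizes used in the shipped tests

The test-suite fixtures are deliberately desk-scale: movies of 50-150
frames at 320-440 px, oracle grids of nine (K, theta_a) combinations at 151
body points and 150 steps per period, and 100-replicate estimator-recovery
loops with 100 bouts each. These sizes were chosen so each stage's check
measures its tolerance comfortably while the full suite runs in about a
minute; all scale linearly if larger studies are simulated.

## Known limitations

* Tip segments of a mask-based centerline are intrinsically the least
  reliable; the first/last ~3 segments rely on extrapolated bridges.
* The amplitude transfer of the full imaging-plus-extraction pipeline is
  gait-dependent at the few-percent level (see above).
* The RFT analysis models only the drag-coefficient ratio; absolute drag
  coefficients, slender-body hydrodynamics and substrate rheology are out
  of scope.
* The ellipse bending index requires the dorsoventral side as metadata; it
  cannot be inferred from a binary head-ROI movie.
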