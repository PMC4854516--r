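# wormbend

Quantitative analysis of *C. elegans* head-bending behaviour and its link to
locomotion mechanics, for researchers who track single worms and record
neural calcium activity.

The package covers the full chain from a binary single-worm movie to the
field's summary statistics:

* **Posture**: centerline extraction from binary masks (boundary →
  head/tail endpoints at the convex-curvature extrema → relaxed midline →
  smoothed tangent angle) and the signed, body-length-normalised curvature
  kymograph κ·L(s, t) over 100 body segments, ventral positive.
* **Head bending**: head curvature as the mean of the anterior 18 segments
  (the first 18% of the body), and the head-bending amplitude as the
  population standard deviation of that trace over the recording — for a
  pure sinusoid of amplitude A this is A/√2. An ellipse-orientation bending
  index in [−1, 1] covers microfluidic head-ROI recordings.
* **Calcium**: background-subtracted ROI traces, per-recording min-max
  normalisation (F − F_min)/(F_max − F_min), and ratiometric traces.
* **Cross-correlation**: lagged Pearson correlograms (±20 s), the control
  group's reference peak lag T_p, and the signed maximum-|r| statistic in a
  1 s window centred on T_p.
* **Locomotion mechanics**: bout segmentation, actual speed V_a, undulatory
  wave speed V_w (phase-lag slope of the kymograph), angle of attack θ_a,
  efficiency η = V_a/V_w, and the resistive-force-theory model at the core
  of the package: in the small-angle limit

  η(θ_a; K) = (K − 1)·q / (1 + K·q),  q = (π²/8)·θ_a²  (θ_a in radians),

  where K = C⊥/C∥ is the drag-coefficient ratio — the single identifiable
  mechanical parameter; K = 1 (isotropic drag) gives no propulsion.
  `fit_drag_ratio()` estimates K by least squares and returns a classed
  model object; `rft_force_balance()` is an independent numerical
  force-balance oracle used to certify the closed form.
* **Synthetic data**: generators for worm movies, bending-locked calcium
  traces and RFT locomotion bouts with known ground truth, so the entire
  pipeline is testable without any downloads.

## Worked example

```r
library(wormbend)

## a 30 s synthetic recording (1 Hz wave, 5 Hz sampling, 5 µm/px)
p   <- wave_params(duration = 30, seed = 42)
mv  <- make_synthetic_movie(p)
kym <- build_kymograph(mv$frames)
kym
#> curvature kymograph: 150 frames x 100 segments, 5 Hz, L = 0.988 mm
#>   kappa*L range: [-4.5, 4.23], 0 missing frames

head_bending_amplitude(head_curvature(kym))
#> [1] 2.512
```

The amplitude 2.51 is the temporal SD of the mean anterior curvature in
κ·L units; the generator's analytic value for this gait is 2.486, so the
imaging-plus-extraction chain reproduces it to about 1%.

```r
## drag-ratio fit on synthetic bouts drawn at K = 1.6
bouts <- make_rft_bouts(K_true = 1.6, n_bouts = 100, seed = 42)
fit   <- fit_drag_ratio(bouts, seed = 1)
summary(fit)
#> Resistive-force-theory drag-ratio fit
#>   C_perp/C_par = 1.614  (bootstrap SE 0.0273)
#>   100 bouts (0 excluded above 60 deg), residual SS = 0.187
#>   residual sd 0.04347, range [-0.1417, 0.1317]
#>   bootstrap 95% CI [1.561, 1.667] (1000 resamples)
plot(fit)          # bouts + fitted curve
predict(fit, newdata = data.frame(theta_a = 30))

## calcium-behaviour coupling recovered by cross-correlation
ca <- make_calcium_traces(kym, lag = 0.6, gain = 2, noise_sd = 0.05, seed = 42)
cg <- cross_correlate(head_curvature(kym), normalize_trace(ca$ventral))
peak_correlation(cg, reference_peak(cg))
#> $value 0.907      $lag 0.6
```

The fit recovers the generating ratio (1.61 vs 1.6) and the programmed
0.6 s calcium lag is recovered exactly, with the expected strong positive
peak for the ventral-like trace (the dorsal-like trace gives the mirror
negative peak).

A thin command-line front end ships in `inst/cli/wormbend.R`
(`simulate`, `track`, `bend`, `xcorr`, `rft`, `run` subcommands), and
`run_pipeline()` chains the stages with CSV/YAML outputs and a run log.

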