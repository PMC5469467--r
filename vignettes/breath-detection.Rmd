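---
title: "Breath detection by inflection points: model, algorithm and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath detection by inflection points: model, algorithm and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantifying breathing — inspiratory time $T_i$, expiratory time $T_e$, tidal
volume $V_t$, peak inspiratory flow (PIF), minute ventilation $\dot V_i$ —
requires knowing where each breath begins and ends. Classical automated
approaches mark inspiration where the flow signal crosses zero, or where the
integrated volume attains its per-breath minimum after an empirical drift
correction. Both break down when the flow baseline wanders, which is exactly
what happens during sleep studies with variable mask pressure (CPAP
dial-downs), mask leaks, or unstable breathing.

`breathseg` implements a drift-robust alternative: the onset of inspiration
is treated as a *physiological landmark* — the instant inspiratory effort
begins — visible as a kink (slope discontinuity) in the airflow signal, or
as the start of the sharp negative deflection in epiglottic pressure
($P_{epi}$). A kink is an extremum of the second derivative, so it can be
located without any reference to the signal's absolute level: additive
baseline drift of low curvature leaves the second derivative, and therefore
the detected onset, essentially unchanged.

## Detection pipeline

For a flow signal sampled at $f_s$ Hz the detector runs three steps
(`detect_breaths()`):

1. **Guide extrema.** A 4th-order Butterworth low-pass at 2 Hz is applied
   forward and backward (zero phase, so timing is unbiased), and peaks and
   valleys at least one breath duration (1 s) apart are found on the
   filtered signal. Peaks and valleys are reconciled to strict alternation.
2. **Segments.** Each valley-to-next-peak stretch of the *raw* signal is the
   rising limb of one candidate breath and contains the inspiratory kink.
   (For $P_{epi}$ the falling peak-to-valley limb is used.)
3. **Inflection.** A cubic smoothing spline is fitted to the raw samples of
   the segment and the fitted second derivative, evaluated at every sample,
   is maximized (minimized for $P_{epi}$); ties take the earliest sample.

Expiratory onsets then come from the signal itself rather than the spline:

* **Flow mode.** Between adjacent inspiratory onsets the flow is integrated
  (trapezoid rule) and the straight line through the two endpoint volumes is
  subtracted — an automatic two-point drift correction anchored at the
  detected onsets. The expiratory onset is the maximum of this corrected
  volume. Without the correction, any nonzero net volume per breath (drift,
  leak, or model asymmetry) pushes the maximum toward the breath boundary;
  with it, the maximum sits where flow crosses its per-breath mean, which
  for a drift-free physiological breath is the usual zero crossing.
* **Pressure mode.** $P_{epi}$ has no volume analogue, so the expiratory
  onset is the first point after the inspiratory pressure nadir where the
  waveform returns to the straight line connecting the pressure values at
  the two adjacent inspiratory onsets. For the final breath the line is
  extended with the mean slope of the preceding breaths.

## The smoothing spline and its units

`smoothing_spline()` fits the natural cubic smoothing spline minimizing

$$p \sum_i (y_i - f(x_i))^2 \; + \; (1-p) \int f''(x)^2 \, dx,$$

the *SP* convention in which $p = 1$ interpolates and $p \to 0$ gives the
least-squares line. The default is $p = 0.95$. The solution is obtained by
the Reinsch algorithm — the interior knot second derivatives $\gamma$ solve
the pentadiagonal SPD system $(R + \lambda Q^\top Q)\,\gamma = Q^\top y$
with $\lambda = (1-p)/p$ — so the second derivative needed by the detector
comes out of the solver directly, at every sample position, with no
numerical differentiation.

A point that matters more than it looks: **the abscissa is in seconds**
($h = 1/f_s$), not in sample indices. The penalized criterion is not
scale-invariant in $x$; the equivalent smoothing bandwidth for uniform
spacing $h$ is approximately $((1-p)\,h/p)^{1/4}$. With $x$ in seconds and
$p = 0.95$ this is $\approx 0.12$ s at 250 Hz and $\approx 0.085$ s at
1000 Hz — a physiologically sensible scale that averages tens of samples of
noise while localizing the kink to within a few hundredths of a second, and
that sharpens as the sampling rate grows. Had the abscissa been sample
indices, the same $p$ would smooth over only $\approx 0.5$ samples at any
rate: the spline would essentially interpolate, and under measurement noise
the second-derivative argmax would be noise-driven (the per-sample slope
jump at a breath onset is an order of magnitude smaller than typical noise).
So the seconds convention is what makes SP = 0.95 meaningful across
sampling rates; it is the package's fixed convention and `sp` should be
re-tuned only together with it.

Two guards make the argmax robust: candidates within 2 samples of a segment
boundary are treated as spurious edge extrema of $f''$ (the natural
boundary conditions pin $f''$ to zero at the ends), triggering one refit on
a 25%-widened window; and degenerate (constant) segments return no onset.

## Synthetic world

`clean_breath_signal()` generates the noise-free model

$$X(t) = Y(t)\,A_1 \sin(2\pi f_1 t / f_s + \varphi) +
         A_2 \cos(2\pi f_1 t / f_s + \varphi),$$

with $t$ in samples: a large sine half-wave ($A_1 = 0.25$ L/s) gated by a
50%-duty-cycle square wave $Y$ riding on a small cosine ($A_2 = 0.1$ L/s).
Each gate opening produces an exact kink whose position is known by
construction — the ground truth for inspiratory onsets. Expiratory truth is
defined *functionally*, by applying the same corrected-volume rule to the
noise-free signal: the model's gate closing is not where a volume-based
expiratory onset lies (flow crosses its per-breath mean about 0.1 period
earlier), so the functional definition is the one a like-for-like
comparison needs.

`add_disturbances()` applies

$$X_{noisy}(t) = \left[X(t) + \xi_n\right]\,
  \left[1 + A_m \sin(2\pi f_m t / f_s + \varphi)\right] + \xi_{trend},$$

* $\xi_n$: white Gaussian noise, SD = `noise_level` $\times \sqrt{A_1}$
  (a 2% noise level gives SD 0.01 L/s). The alternative reading — SD
  proportional to $\sqrt{|X(t)|}$ pointwise — is available as
  `noise_sd_mode = "instantaneous"`; the constant default gives stationary
  noise of the same nominal scale.
* amplitude modulation: $A_m = 0.5$ at $f_m = 0.005$ Hz, i.e. breath
  amplitudes wander slowly between 50% and 150% over ~3-minute cycles. The
  modulated, noise-free signal is kept as the `reference` channel: true
  parameter values are read from it, so modulation affects both sides of a
  comparison equally.
* $\xi_{trend}$: fractional Gaussian noise (`fractional_gaussian_noise()`,
  Davies–Harte circulant embedding, exact autocovariance
  $\gamma(k) = \tfrac{\sigma^2}{2}(|k{+}1|^{2H} - 2|k|^{2H} + |k{-}1|^{2H})$)
  with SD 0.1 and Hurst exponent 0.9, sampled **once per breath** at the
  true onsets and linearly interpolated. This models the breath-by-breath
  wander of the flow baseline: a persistent ($H = 0.9$) random level that
  drifts between breaths but is smooth within one. Sampling the FGN at the
  full signal rate instead (`trend_per = "sample"`) turns it into a second,
  large noise floor — sample-to-sample increments of ~0.07 L/s — which is a
  different physical claim (sensor noise, not baseline drift) and
  overwhelms every breath-scale statistic; it is kept available but is not
  the default world.

`generate_validation_dataset()` concatenates ten constant-frequency
segments, 8 to 17 breaths/min, of `n_breaths_per_segment` breaths each
(default 100, hence 1000 breaths). Every segment starts at phase 0 and
spans an integer number of periods, so the carrier is continuous across
boundaries and each boundary *is* a true onset; the white noise, the
modulation sinusoid and the per-breath trend are all drawn once over the
global record so that no artificial discontinuities appear at segment
joins. With the same seed the dataset is bit-reproducible.

What the generator does *not* emulate: apneas and hypopneas, sighs,
swallows, mask-leak transients, cardiogenic oscillations, or genuinely
variable within-subject breath morphology. A green synthetic test
establishes that the detector locates slope discontinuities of known
position under drift, modulation and stationary noise — not that it handles
every clinical artifact; the sub-breath rejection rules below are the main
defenses carried over to messy data.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `cutoff_hz` | 2 | Hz | low-pass guiding peak/valley detection; must exceed the breathing frequency by a comfortable margin and stay below Nyquist |
| `min_breath_s` | 1 | s | minimum peak separation = shortest credible breath |
| `sp` | 0.95 | – | smoothing parameter; bandwidth $((1-p)/(p f_s))^{1/4}$ s |
| `min_prominence_frac` | 0.05 | – | peak prominence floor, fraction of the filtered signal's IQR |
| `min_rise_frac` | 0.10 | – | candidate limbs with filtered excursion below this fraction of the record's median excursion are rejected as sub-breath wiggles |
| `drift_correct` | TRUE | – | two-point volume correction per breath |
| `noise_level` | 0.02 | – | generator white-noise fraction |
| `trend_sd`, `hurst` | 0.1, 0.9 | L/s, – | baseline-wander scale and persistence |

The two rejection rules deserve a note because they are *additions* the
bare three-step pipeline needs on drifting signals. Baseline wander
occasionally creates a shallow valley–peak pair inside a long expiration
that survives both the 1 s separation and the prominence floor; locating an
"inflection" there yields a false breath whose neighbors then carry
multi-second timing errors. Real breaths in a record share an amplitude
scale, so an excursion an order of magnitude below the record's median is
not a breath — `min_rise_frac` encodes exactly that, adaptively, with no
absolute threshold to tune.

## Numerical choices

* Trapezoidal integration for volume (second-order accurate; a step
  waveform's half-sample edge effect is the known cost).
* All argmax/argmin ties break to the earliest index.
* Peaks on plateaus take the first sample of the plateau.
* The zero-phase filter initializes both passes at the local signal level
  and odd-extends the edges, so constants pass through exactly and edge
  transients are confined to the padding.
* The FGN circulant embedding pads to the next power of two and refuses to
  proceed if the embedding eigenvalues are materially negative (they are
  not, for any $H \in (0,1)$ on these sizes); tiny negative rounding
  residue is clipped.
* Seeded generation uses a local RNG stream and restores the caller's
  `.Random.seed`.

## Known limitations

* The spline second-derivative argmax carries a small deterministic bias on
  curved backgrounds: the carrier's curvature just after the kink exceeds
  that just before, pulling the smoothed $f''$ peak earlier by roughly
  $\omega^2 b^3$ ($\omega$ the breathing angular frequency, $b$ the
  smoothing bandwidth) — about 1 sample at 12 breaths/min and 3 samples at
  16–17 breaths/min, i.e. 3–12 ms. This is intrinsic to smoothing at the
  scale that noise robustness requires and is far inside the ~0.03 s
  stochastic onset error at realistic noise.
* Detection quality degrades with noise and improves with sampling rate;
  below 250 Hz and above 5% noise, missed breaths climb quickly (the
  reduced-scale study in the test suite maps this surface).
* The first breath of a record has no preceding valley, so its onset cannot
  be detected — one structurally missed breath per record.
* $P_{epi}$ mode assumes pressure falls sharply at effort onset; conditions
  that decouple flow and pressure landmarks (e.g. severe intrinsic PEEP)
  break the alignment assumption.
* Parameters extracted from noisy recordings should use the smoothed-flow
  option (`smooth_hz = 2`, the default in `validation_report()`): the
  maximum of a noisy signal is biased upward by the noise's extreme values,
  which matters for PIF.
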