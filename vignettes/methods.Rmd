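---
title: "Methods: conventions, design choices and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conventions, design choices and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the mathematical conventions the package commits
to, the design decisions that are not forced by the method itself, and
how the synthetic-data defaults were calibrated. Code chunks are
illustrative and not evaluated at build time.

## 1. Signal model and phase convention

A pixel whose receptive field sits at normalized position $x \in [0, 1]$
along the sweep axis responds once per sweep. With drift frequency $f$
(angular $\omega = 2\pi f$) and hemodynamic delay $\tau$, the absorbance
signal during a forward sweep is modelled as

$$\Delta A(t) = a \, \big(1 - \cos(\omega t - \varphi)\big)/2 \cdot s,
\qquad \varphi = 2\pi x + \omega\tau,$$

where $s$ is the response sign (+1 for absorbance, since activation
*increases* absorbance under red light; reflectance dips). The backward
sweep replaces $x$ with $1 - x$.

`trial_phase_map()` projects each pixel trace onto the stimulus
frequency with the conjugate kernel,

$$z = \frac{2}{N} \sum_n \Delta A(t_n)\, e^{+i\omega t_n},$$

so that `Arg(z)` *is* the response lag $\varphi$ (up to the response
sign) and `Mod(z)` is the response amplitude. Phases are always wrapped
to $(-\pi, \pi]$ by `wrap_phase()`.

## 2. Delay cancellation

For a forward/backward pair with complex responses $w_f, w_b$:

- $\mathrm{Arg}(w_f) = 2\pi x + \omega\tau$ (mod $2\pi$, up to sign),
- $\mathrm{Arg}(w_b) = 2\pi(1 - x) + \omega\tau$,

so the *product* $w_f w_b$ has argument $2\omega\tau$ independent of
$x$. `absolute_phase()` estimates a single global delay phase
$\delta = \mathrm{Arg}\big(\sum_{\text{pixels}} w_f w_b\big)$
(amplitude-weighted, which suppresses background pixels) and recovers
the retinotopic phase as $\theta = \mathrm{Arg}(w_f) - \delta/2$.

Halving $\delta$ is ambiguous by $\pi$. The ambiguity is resolved by
picking the branch that puts the median retinotopic phase of
high-amplitude pixels inside the stimulus span — the wrong branch maps
the whole response off-span. The recovered delay in seconds is reported
as an attribute. `phase_to_degrees()` then maps phase linearly onto the
configured azimuth or elevation span.

With the default 2.5 Hz scaled acquisition the first frame inside a
trial samples the sweep 0.2 s (half a frame period) after onset; this
constant enters both sweep directions identically, cancels out of
$\theta$, and appears only as a constant offset in the reported delay.

## 3. Spectral leakage and the exact-cycle protocol

The nominal protocol (18 s sweeps at 0.055 Hz) has $18 \times 0.055 =
0.99$ stimulus cycles per sweep-trial: the projection window is not an
integer number of cycles, so the single-frequency projection leaks, and
the recovered phase acquires a small delay-dependent bias (up to
~0.013 rad across 1–6 s delays). This is a property of the protocol
arithmetic, not of the implementation.

Phase-*precision* tests therefore use an exact-cycle variant — 20 s
sweeps at 0.05 Hz sampled at 2.5 Hz, i.e. exactly 50 frames per cycle —
where delay invariance holds to $10^{-14}$ rad and noiseless recovery is
exact to $10^{-12}$ degrees. Everything else (QC, VFS, segmentation,
reliability) is exercised under the nominal protocol, whose ~0.01 rad
(~0.2°) leakage bias is negligible against the 0.5° accuracy scale.

## 4. Smoothing design

Three distinct smoothing steps, all NaN-aware normalized Gaussian
convolution (`smooth_map()`):

1. **Complex pre-smoothing** (`presmooth_sigma = 2` in
   `build_axis_map()`): the averaged phase map is smoothed in the
   complex plane (real and imaginary parts separately). This is an
   amplitude-weighted local phase average — noise-dominated pixels carry
   little amplitude and little weight. It denoises phases without
   needing an amplitude mask, keeping the map defined everywhere
   (important for the noise-ROI detectability analysis). The cost is a
   small bias at area borders (≤ 8° in the worst noiseless corner), so
   noiseless oracle checks are run with `presmooth_sigma = 0`.
2. **Gradient smoothing** (`sigma` in `visual_field_sign()`): smooths
   azimuth/elevation before taking gradients. The scale must follow the
   geometry: the default 4 px suits a full-scale (≥ 128 px across
   several mm) field, while the scaled 96 px test field uses 1.5 px —
   at 4 px the kernel is comparable to the semi-minor axis of the
   smallest simulated area and washes out its sign.
3. **Sign-map post-smoothing** (`post_sigma = 4`): the VFS normalizes
   gradients, so background pixels get O(1) random signs; averaging over
   a 4 px neighbourhood drives incoherent signs toward 0 while coherent
   area signs survive, which is what makes |S| thresholding work.

## 5. Trial quality control

The QC statistic is the spatial variance of each trial's amplitude map,
normalized by the batch maximum; trials below `qc_threshold` (default
0.6) are discarded. A trial with no stimulus-locked signal has a
spatially flat amplitude map (variance near 0), while a responsive trial
concentrates amplitude in the visual areas. Under the calibrated noise
model the two populations separate cleanly (bad ≤ 0.28, good ≥ 0.74
normalized), giving 100 % detection with no false discards; the 0.6
threshold sits in the middle of the gap.

## 6. Segmentation

`segment_areas()` thresholds |S| (default 0.3), labels 4-connected
components, fills enclosed holes, drops components below `min_size`, and
reports per-segment sign, pixel count and centroid (px and µm).
`match_segments()` assigns each reference region the segment with the
largest fractional overlap. Mirror/non-mirror alternation of adjacent
areas is inherited from the signs of the ground-truth area Jacobians.

## 7. Reliability analyses

`subsample_average()` draws `n` pair-trials without replacement,
rebuilds the maps, and repeats; `centroid_error_curve()` tracks the
distance (µm) between each subsampled V1 centroid and the full-data
centroid; `min_trials_for_criterion()` reports the smallest `n` from
which the error stays below a criterion (default 100 µm, a useful bound
for craniotomy targeting). `roc_detectability()` computes, per area and
trial count, the AUROC of sign-corrected VFS values inside the area
versus a dilation-margin noise region outside all areas
(`noise_roi_outside()`), using the rank (Mann–Whitney) AUROC — which the
tests verify against an explicit threshold-sweep ROC integration.

## 8. Laminar LFP validation

`assign_layers()` finds the channel with the earliest response latency
(the layer 4 current sink), takes channels within ±`l4_halfwidth`
(100 µm) as layer 4, shallower as superficial, deeper as deep.
`lfp_preferred_position()` averages tuning curves across the group's
channels *before* taking the argmax (a single-channel argmax-first rule
is unstable when channels disagree). `isi_vs_lfp_stats()` reports mean
absolute error, $r^2$ and the correlation p-value between ISI-predicted
and LFP-preferred positions.

The LFP generator gives deep channels a *shared* per-recording offset
from the ISI-predicted position (plus per-channel jitter on all
channels), modelling a systematic laminar displacement of deep-layer
receptive fields; a shared offset does not average out within a
recording, so deep-layer agreement is genuinely worse than superficial —
matching the use of superficial layers for validation.

## 9. Synthetic-data calibration and scaled problem sizes

The generator defaults were frozen before the acceptance suite was run,
after calibrating on held-out seeds:

- modulation 0.004 of baseline (sub-percent regime), baseline 40 000
  counts, 5 s baseline window;
- white noise SD 0.005 absorbance, pink (coarse-grid) noise SD 0.002 —
  large enough that single pair-trial maps are visibly noisy (the error
  curve decreases with trial count), small enough that QC separates
  planted bad trials cleanly;
- 10 % planted bad trials (signal-free sweeps);
- test geometry 96 px at 2.5 Hz with 10 blocks per direction
  (100 sweep-trials per direction), a deliberate scale-down of the
  full protocol (≥ 128 px at 10 Hz) chosen so the whole suite runs in
  minutes while preserving cycles per sweep, modulation depth,
  noise-to-signal ratio and trials per session.

Quantities that depend on a noise realization (per-area AUROC, QC rates)
fluctuate across seeds; the headline script (`scripts/acceptance.R`)
recomputes them for any `--seed`.
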