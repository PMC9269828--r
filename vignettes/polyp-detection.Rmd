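---
title: "Microwave colonoscopy polyp detection: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwave colonoscopy polyp detection: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colowave)
```

## The detection problem

A ring-shaped switchable antenna array mounted on a colonoscope tip
acquires, at each 4 mm step along the colon axis, the complex transmission
S-parameters of 24 transmitter–receiver pairs at a single frequency of
7.6 GHz. Neoplastic tissue has elevated dielectric properties relative to
healthy mucosa — at these frequencies roughly 30% higher relative
permittivity and 90% higher conductivity — so a polyp anywhere on the
360° perimeter perturbs the measured fields, including in locations the
endoscope camera does not see. The task is to turn the stream of frames
into a simple binary alarm per frame ("polyp here") with high sensitivity
and useful specificity.

`colowave` implements the three-stage pipeline:

1. **Calibration** — automatic temporal subtraction: for each frame,
   subtract the most similar previously acquired frame, selected by the
   modified Hausdorff distance between the two frames' S-parameter sets in
   the complex plane. Wall clutter, fold geometry and angulation effects
   that change slowly along the trajectory cancel; the abrupt appearance of
   a lesion does not.
2. **Focusing** — monofocusing backprojection of the calibrated scattered
   field onto a cross-sectional pixel grid: pixel `r` accumulates
   `Es^2 * J1(2k|r_R - r|) * exp(1i(2k|r_R - r| + phi))` over the 24 pairs,
   with `J1` the order-one Bessel function, `k = 2*pi*f/c` the free-space
   wavenumber (the lumen is insufflated, so propagation is through
   air-like CO2), and `phi` the transmitter–receiver angular separation.
   The image magnitude is a dielectric-contrast map; its maximum is the
   frame's summary statistic `y`.
3. **Detection** — one-step exponential-smoothing forecasting of `y` with
   an outlier band: level `s' = alpha*y + (1-alpha)*s`, smoothed absolute
   deviation `w' = alpha*|y - s'| + (1-alpha)*w`, band `s' ± delta*w'`. A
   frame whose `y` lies strictly above the band forecast from the previous
   state raises the alarm. Because the trigger compares `y` only with the
   history of its own trajectory, absolute amplitude scales — which are not
   comparable between specimens — drop out: multiplying every `y` by a
   positive constant leaves the alarm set unchanged.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.3 | smoothing constant in [0, 1]; memory of the level/deviation estimates (≈ 1/alpha frames) |
| `delta` | 3 | band half-width in smoothed-deviation units; larger = fewer alarms |
| `warmup` | 3 frames | scored frames with alarms forced off while estimates settle |
| `metric` | `"mhd"` | frame similarity for reference selection; `"chebyshev"` (max channel modulus difference) is the literal max-norm alternative |
| `grid` | 45 mm half-width, 1 mm pitch | image window covering a 90 mm colon diameter; odd pixel count keeps the origin on a pixel centre |
| `field_power` | 2 | backproject `Es^2` (monofocusing convention); 1 backprojects the field itself |
| `tolerance_frames` | 1 | dilation of lesion extents when labelling frames, absorbing the manual registration of lesion positions |
| `pool_window` | unlimited | number of recent frames eligible as calibration references |

`alpha` and `delta` trade sensitivity against specificity: raising `delta`
can only shrink the alarm set (a property the tests assert as exact set
inclusion), so sensitivity is non-increasing and specificity non-decreasing
along a `delta` sweep. The defaults were fixed once on the bundled
synthetic ensemble to hold sensitivity at its maximum while keeping
frame-level specificity near 90%; a deployment against real acquisitions
would re-run such a sweep on measured data.

## What the synthetic generator emulates

No raw ex vivo S-parameter recordings are publicly available, so the
package ships a Born single-scattering simulator that reproduces the
*statistical structure* the algorithm relies on, not antenna
electromagnetics:

* **Wall clutter** — a deterministic specular-like term per pair,
  `exp(-2i k w)/w` with `w` the antenna-to-wall distance at the pair's
  midpoint bearing. It is constant for a straight constant-radius lumen
  (so temporal calibration cancels it *exactly*, which the tests assert)
  and drifts smoothly under fold modulation or centre-line curvature.
* **Angulations** — a sinusoidal lateral drift of the lumen centre line
  (default amplitude 3 mm in the curved ensemble cases), making the wall
  distance direction-dependent and slowly varying, the situation temporal
  calibration is meant to survive.
* **Polyps** — point scatterers with complex amplitude
  `tau * size/10`, where `tau = (eps*_lesion - eps*_background)/eps*_background`
  is the two-tissue dielectric contrast at 7.6 GHz (defaults: healthy
  mucosa eps_r = 50, sigma = 7 S/m; neoplasm 30%/90% above). The linear
  size scaling reflects that the array sees an effectively 2D slice of a
  superficial protruding lesion. Axially the response follows a
  super-Gaussian `exp(-((z - z_c)/(size/2))^4)`: near-flat over the lesion,
  steep at its edges, so the detectable ramp stays within about one frame
  of the true extent.
* **Debris** — optional weak scatterers (default strength 0.05) with short
  axial extent, emulating suboptimal colon cleaning.
* **Noise** — i.i.d. circular complex noise per S-parameter,
  `noise_sigma = 3` by default (a few percent of the clutter magnitude).
  The level was calibrated once so that the polyp-free image-maximum
  variation sits far below a 30 mm polyp's peak — the regime the detector
  assumes — and is exposed in the scene specification.

What it does **not** model: antenna radiation patterns and coupling,
multiple scattering, tissue heterogeneity beyond the two-tissue contrast,
mucus films, peristalsis, or quantitative permittivity recovery. Passing
the synthetic acceptance ensemble therefore shows that the *algorithm*
behaves as designed under its own premises; it is not evidence about any
particular hardware.

## The bundled evaluation ensemble

`ensemble_scenes()` builds 15 scenes mirroring the published ex vivo
examinations: lengths 80–330 mm, one lesion each of 10–65 mm, three curved
cases (11, 13, 14), one debris case (12), lesions centred at 60% of the
trajectory (clamped inside the sample) with bearings rotating around the
ring. With 4 mm steps this is about 960 frames; the full
simulate–calibrate–reconstruct–detect–evaluate cycle takes well under a
minute on one CPU, which is also the problem size used by the test suite.
Sensitivity is counted per lesion (a lesion is detected if any alarm frame
overlaps its extent dilated by one frame) and specificity per scored
healthy frame. This hybrid unit reproduces the reporting style of per-case
percentages with exact-100 sensitivities and fractional specificities; the
counting unit is switchable (`positive_unit = "frame"`).

## Numerical and design choices

* **Frame-similarity point sets.** The modified Hausdorff distance is
  computed between the two frames' 24 points (Re, Im) in the complex
  plane, preserving per-channel magnitude and phase. How the original
  system formed point sets from S-parameters is not recoverable; the
  channel-wise Chebyshev reading is kept as an option, and reference
  selection ties break towards the most recent frame.
* **Reference pool.** All previous frames are eligible (no window) by
  default; frames already flagged as lesions are *not* excluded from the
  pool. Deep inside a long lesion the reference is then often another
  lesion frame and the residual shrinks — the alarm fires on lesion
  *entry*, which suffices for lesion-level detection and mirrors the
  "parking sensor" interaction model.
* **Frame 0** has no possible reference: it is never calibrated or scored
  and is reported with `alarm = FALSE`.
* **Focuser sums.** The double sum runs over all 8 transmitters and the 3
  measured receivers per transmitter — the only reading consistent with
  the 24-pair plan. Only the receiver distance enters the Bessel weight
  and phase, exactly as the method is printed; `Es^2` is the complex
  square (switchable via `field_power`). `J1(0) = 0` suppresses the
  receiver positions naturally, so no guard region is needed.
* **Detector recursions.** The band uses the exponentially smoothed
  absolute deviation `w' = alpha*|y - s'| + (1-alpha)*w` scaled by
  `delta` — the standard forecasting-band construction; alternative
  groupings of the printed recursion admit negative widths and were
  rejected. The deviation residual against the previous level is available
  (`deviation_ref = "previous"`). Initialisation: level = first scored
  `y`, deviation = 0, three warm-up frames. The trigger is one-sided
  (upper band) by default since lesions only raise the image maximum;
  `two_sided = TRUE` is available. Comparisons are strict: `y` exactly on
  the band edge does not alarm.
* **Geometry.** Transmitting and receiving rings are treated as coplanar
  for 2D slice imaging (the physical axial offset is second-order here and
  kept as a field); antenna 0 sits at angle 0 with indices
  counter-clockwise, and only relative angles matter.
* **I/O.** Complex values are stored as separate real/imaginary CSV
  columns with 17 significant digits, so `read_trajectory(write_trajectory(t))`
  is bit-exact and repeated writes are byte-identical. Reconstructed image
  stacks are written as long-format CSV (frame, x, y, amplitude) — a
  plain-text container that any analysis stack ingests directly.

## Known limitations

* The simulator's clutter and noise levels are stand-ins; absolute
  amplitudes carry no physical units, only their ratios matter.
* Detection quality near the very start of a trajectory is limited by the
  warm-up: a lesion beginning before frame `warmup + 1` cannot alarm
  inside its extent.
* The focuser localises to roughly a quarter wavelength (about 10 mm at
  7.6 GHz); the image is a contrast map, not a quantitative permittivity
  reconstruction, and bearing information is coarse (per antenna sector).
* Very large lesions relative to the sample length leave few healthy
  frames, making per-case specificity a noisy quantity (it is reported,
  but pooled counts are the primary metric).
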