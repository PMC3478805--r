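---
title: "Measuring navicular drop with a capacitive strain sensor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring navicular drop with a capacitive strain sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navdrop)
```

## The measurement problem

The dynamic navicular drop (ND) is the sagittal lowering of the navicular
tuberosity from heel strike (HS) to its lowest point (NHL) during the
stance phase of gait — a standard clinical proxy for midfoot pronation.
Healthy adults average about 5.3 mm (SD 1.8 mm); problematic feet reach
15 mm. Video marker systems measure it well on a treadmill and bare feet,
but say nothing about what the foot does inside a shoe.

A thin dielectric-electroactive-polymer (DEAP) strain sensor glued to the
medial side of the foot changes capacitance linearly with the distance
between its two attachment points, which tracks the navicular height. This
package implements the complete processing chain for such a sensor:

1. **Calibration** — least-squares (or two-point) capacitance-to-
   elongation line, drift auditing, and drift-to-accuracy propagation.
2. **Synchronization** — the sensor samples at 200 Hz; the video reference
   runs at 114 Hz and photographs a sync box whose 16 LEDs display the
   current sensor sample number in binary-reflected gray code. Decoding
   those words per video frame aligns the streams sample by sample.
3. **Placement analysis** — local foot frame from two reference markers,
   per-marker displacement point clouds, their principal (major) axes, and
   a perpendicularity score for candidate attachment sites.
4. **Event detection** — per-step HS / NHL / toe-off on the video-derived
   height signal; sensor-side HS (windowed local minimum) and NHL (strain
   argmax); a standalone mode for in-shoe recordings with no reference.
5. **Statistics** — per-step drops from both streams, session means with
   95% t-intervals, Pearson correlation with t-transform p-values, mean
   differences, and Welch test–retest comparisons.
6. **Simulation** — a gait/sensor generator with exact ground truth, so
   every stage is testable without hardware.

## The synthetic gait and sensor model

No public recordings of this instrument exist, so the package ships a
generator whose outputs have the same shape, units, rates and quantization
as the real acquisition chain, plus a truth record.

**Height template.** Each stride of duration $1/f_c$ (default cadence
$f_c = 0.93$ strides/s, a 5 km/h preferred walking speed) is a piecewise
raised-cosine: height at baseline (40 mm) at HS, a $C^1$ descent to a
per-stride depth $d_k$ at a fixed fraction of stance (default half of a
62% stance), a $C^1$ recovery to baseline at toe off, and a flat swing.
$d_k \sim \mathcal N(\mu_{ND}, \sigma_{ND})$ truncated at zero (defaults
5.0 and 0.8 mm); the truth ND of step $k$ is exactly $d_k$. Published
waveforms of this instrument show only measured curves, no equation; the
raised-cosine template was chosen as the simplest smooth shape that
exercises realistic event detection, and the flat swing reflects the
near-flat strain visible between steps on such recordings. Half a stride
of quiet lead-in/out pads the trial.

**Transduction.** Sensor elongation is
$e(t) = g\,[\mathrm{NH}_0 - \mathrm{NH}(t)] + c(t)$ with geometry gain $g$
(default 1) and a crosstalk term $c(t)$; capacitance is
$C = C_0 + e/s$ quantized to 0.13 pF steps at 200 Hz (the acquisition
chain's resolution and rate), with optional Gaussian noise. The default
slope $s = 0.1$ mm/pF gives 0.013 mm of elongation per quantum —
consistent with the high capacitance-per-strain of DEAP strips and with
the instrument resolving sub-millimetre drops. Elongation beyond 50% of
the 40 mm rest length would damage the material, so the generator raises
an over-strain error rather than clipping (a 20 mm calibration sweep is
exactly 50% strain).

**Crosstalk.** The sensor hugs the skin and picks up frontal-plane motion
the single-camera reference cannot see. We model it as a stride-locked,
$C^1$ waveform: raised-cosine rise over the first 45% of the stride,
plateau, and a steep raised-cosine fall over the final 10%, exactly zero
at every heel strike. Two consequences are intended: (a) the steep
pre-HS fall reproduces the characteristic strain drop into heel strike
seen on real sensor records, which is what makes the sensor-side HS a
well-defined local minimum despite quantization; (b) per-stride amplitude
scaling (uniform 0.5–1.5 of the nominal amplitude, default 0.5 mm)
injects stride-to-stride disagreement between the streams, mirroring the
scatter such validations report. The lead-in carries the tail of a
virtual stride so the first heel strike looks like every other one.
Crosstalk is *signal*, not noise: amplitude-accuracy checks set it to
zero; timing checks keep it.

**Camera stream.** Frames at 114 Hz carry pixel positions (image
convention, y down, default 0.2 mm/px) of two static reference markers
and the navicular marker, Gaussian pixel noise, the 16-bit gray word of
the nearest strain-sample index (modulo $2^{16}$), and two always-on
fiducial bits. Marker noise default is 0.1 mm (half a pixel).

**What the generator does not emulate:** soft-tissue artifact, marker
occlusion and relabeling, camera lens distortion, sensor hysteresis and
creep, temperature drift, and non-stationary gait. Passing tests
demonstrate the *pipeline's* correctness on signals with the stated
structure, not the instrument's clinical validity.

## Numerical and design choices

**Calibration orientation.** Extension is regressed on capacitance, so
the slope is directly in mm/pF. Two-point calibrations carry no
R-squared — a two-point line is exact by construction and a 1.0 would be
a meaningless quality claim. Drift is reported as absolute percent of the
reference slope; the worst-case drop error it implies is
$\mathrm{ND} \times \mathrm{drift}/100$.

**Sync decoding.** Gray words are stored LSB-first (the physical LED
ordering is a free convention). Decoded sample numbers are unwrapped
modulo $2^{16}$ by nearest continuation at the nominal 200/114 ≈ 1.754
samples/frame; a frame whose jump deviates from expectation by more than
3 per-frame increments is invalidated individually. Fewer than two valid
frames is a hard error.

**Upsampling.** Linear interpolation (a cubic option exists but linear is
the tested default — monotone, no ringing at the sharp heel-strike
feature). The displayed sample numbers are integers, so raw decoded
positions carry up to half a sample of rounding jitter; by default the
abscissae are refined by a linear clock fit across the valid frames,
which removes the jitter when both clocks are steady and falls back to
the raw indices when fit residuals exceed half a sample.

**Step segmentation.** Stride period from the autocorrelation peak in the
0.4–2 s lag band (walking cadences); one anchor per stride at the
dominant periodic feature (deepest trough for a height signal, highest
peak for elongation — whichever deviates more from the median); anchors
must reach 25% of the maximal deviation (rejects flat tails); boundaries
midway between anchors.

**Event rules.** On the height signal: NHL is the step's argmin; HS is
the last pre-descent sample still at the plateau (90th percentile of the
pre-minimum segment, 0.5%-of-range tolerance), localized via the final
crossing of plateau minus 5% of the step range; TO is the first
post-minimum return to within that 5% threshold. Flat steps (< 0.1 mm
range) are skipped with a warning, never fabricated. On the sensor
stream: HS is the elongation minimum within ±10% of the step *duration*
around the video HS (the published ±10% "of a step length" rule, read
temporally — the only reading that defines a window; whether the original
meant stride or stance duration is unstated, we use stride), NHL the
elongation argmax in the step. All ties break to the earliest index, so
results are deterministic. Event localization runs on a 5-sample
(25 ms) moving average, but reported values are always read off the raw
series at the detected indices — smoothing steers *where*, never *what*.

**Standalone (in-shoe) mode.** With no video reference, steps come from
segmentation of the elongation signal itself; HS is the bottom of the
characteristic pre-rise strain drop and NHL the step argmax. Output is
flagged `mode = "standalone"` because the corresponding published events
were hand-annotated: there is no algorithmic ground truth for this mode
beyond the simulator.

**Statistics.** Session CIs are t-based on per-step values (the source
material does not state its CI method). The paired comparison uses the
Pearson product–moment correlation with the exact t-transform p-value.
Test–retest uses Welch's unpaired two-sample t-test: the two sessions
contain different step counts (63 vs 88 in the published table), which
precludes pairing. All p-values are two-sided at the conventional 5%
level. The drop estimate from the sensor is the calibrated elongation
change HS→NHL taken directly in mm — the minimal reading consistent with
reporting sensor ND in millimetres alongside video ND.

## Problem sizes and verification

The test suite and the acceptance script verify, among others:

* gray encode/decode round-trip and the one-bit-per-increment property
  exhaustively over all 65,536 words;
* least-squares calibration against brute-force normal equations on 1000
  random sweeps (relative agreement 1e-10);
* cross-timeline event-time transfer on a noiseless ~70 s trial to within
  half a 200 Hz sample (2.5 ms);
* end-to-end mean-drop recovery on 60–64-step trials: within 0.1 mm of
  truth noiseless, within 0.3 mm under one capacitance quantum and half a
  pixel of marker noise;
* strictly decreasing two-stream correlation across crosstalk amplitudes
  0, 0.5 and 1.5 mm (500 steps each);
* 5% ± 1.5% type-I error of the test–retest comparison over 1000 null
  replicates.

Trial lengths of 60–64 steps mirror a ~70 s treadmill recording at
preferred walking speed; the 500-step runs give the correlation
monotonicity check enough resolution to be strict. These sizes were
chosen to make the stochastic checks decisive at the stated tolerances.

## Known limitations

* The segmentation assumes quasi-periodic walking; running gaits are not
  tuned for (the parameters permit faster cadences, but defaults and
  tests cover walking).
* The placement module consumes marker coordinates; it does not detect
  anatomical landmarks, and the published ~20 mm anatomical offsets of
  the recommended attachment sites are subject-specific inputs, not
  outputs. The perpendicularity criterion is exposed both as the
  axis-vs-sensor-line score and as the between-axes angle, because the
  two readings differ on real feet (the published between-axes angle at
  the recommended sites is ≈120°, not 90°) and the original optimization
  target is ambiguous.
* The timer-circuit frequency stage is modeled abstractly (capacitance
  is emitted directly); no public circuit constants exist for the
  frequency-to-capacitance map.
* Real validation data of this instrument show far lower two-stream
  correlations (≈0.4) than the simulator produces, because real feet add
  soft-tissue and frontal-plane effects the crosstalk model only
  sketches. The simulator is a correctness harness, not a realism claim.
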