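# navdrop

Measuring the **dynamic navicular drop** — the sagittal lowering of the
navicular bone from heel strike (HS) to its lowest point (NHL) during
stance, a standard clinical measure of midfoot pronation — from a thin
capacitive (DEAP) strain sensor worn on the medial side of the foot, with
a marker-based video system as reference. Unlike camera systems, the
strain sensor keeps working inside a shoe.

The package implements the full processing chain for such an instrument,
plus a synthetic gait/sensor generator with exact ground truth so every
stage runs and is tested without hardware:

| Stage | Functions |
|---|---|
| Calibration (mm/pF line, drift audit) | `fit_calibration()`, `two_point_calibrate()`, `apply_calibration()`, `slope_drift()`, `drift_to_accuracy()` |
| Gray-code stream synchronization (200 Hz sensor / 114 Hz video) | `gray_encode()`, `gray_decode()`, `decode_frames()`, `upsample_to_strain_timeline()`, `transfer_time()` |
| Sensor-placement geometry | `to_local_frame()`, `displacement_cloud()`, `major_axis()`, `axis_angle_between()`, `score_attachment_pair()` |
| Gait events (HS / NHL / TO) | `segment_steps()`, `detect_mvsa_events()`, `detect_pbs_hs()`, `detect_pbs_nhl()`, `detect_inshoe_events()` |
| Per-step drops and validation statistics | `nd_from_mvsa()`, `nd_from_pbs()`, `session_summary()`, `paired_comparison()`, `test_retest()` |
| Simulation with ground truth | `gait_profile()`, `sensor_model()`, `generate_trial()` |
| Files and workflows | `read_strain_csv()`, `read_marker_csv()`, `run_workflow()`, `navdrop_cli()` (CLI script in `exec/navdrop`) |

## The core quantities

Per step *k*, both streams yield a drop estimate:

* video: `ND_k = NH(hs_k) − NH(nhl_k)` from the marker-derived navicular
  height on the sensor timeline (after gray-code synchronization and
  upsampling);
* sensor: `ND_k = e(nhl_k) − e(hs_k)` from the calibrated elongation
  `e = slope · C + intercept` (mm), with sensor HS the local elongation
  minimum within ±10% of the step duration around the video HS and
  sensor NHL the elongation argmax in the step.

Sessions are summarized as `mean ± t(0.975, n−1) · SD/√n`, streams are
compared by the Pearson product–moment correlation with its t-transform
p-value `t = r√((n−2)/(1−r²))`, and test–retest sessions by Welch's
unpaired t-test. A slope drift of *p* percent between calibrations bounds
the drop error by `ND · p/100` (e.g. 4% on a 10 mm drop → 0.4 mm).

## Worked example

Simulate a ~65 s walking trial (60 steps, true mean drop 5.0 mm, SD
0.8 mm, realistic quantization, noise and frontal-plane crosstalk), then
run the full two-stream analysis:

```r
library(navdrop)
profile <- gait_profile(n_steps = 60, nd_mean_mm = 5.0, nd_sd_mm = 0.8, seed = 42)
sensor  <- sensor_model()           # 0.13 pF quantization, 200 Hz, 0.5 mm crosstalk
trial   <- generate_trial(profile, sensor)
trial
#> <simulated_trial> 60 steps, true mean ND 4.98 mm, 13119 strain samples, 7478 frames

model <- fit_calibration(simulate_calibration_sweep(sensor))
model
#> <calibration_model> slope 0.100002 mm/pF, intercept -10.0004 mm, R^2 1.000000 (n = 41)

res    <- analyze_trial(trial$strain_series, trial$marker_series, model)
report <- trial_report(res$nd_mvsa_mm, res$nd_pbs_mm, seed = 42L)
report
#> <trial_report> 60 paired steps
#>   video mean ND  5.08 mm (95%CI 4.84; 5.32)
#>   sensor mean ND 5.35 mm (95%CI 5.11; 5.59)
#>   mean difference -0.27 mm (95%CI -0.32; -0.22)
#>   Pearson r 0.977 (p = 1.097e-40)
```

The true mean drop of this trial is 4.98 mm. The video estimate (5.08 mm)
recovers it to within a tenth of a millimetre plus sampling error; the
sensor estimate (5.35 mm) additionally carries the frontal-plane
crosstalk the sensor genuinely measures and the camera cannot see, which
is also what pulls the per-step correlation below 1. Set
`sensor_model(crosstalk_mm = 0)` and both streams agree with the truth to
within quantization.

The same chain is available from the shell:

```sh
exec/navdrop simulate --out trial/ --seed 42
exec/navdrop analyze  --strain trial/strain.csv --markers trial/markers.csv \
                      --calibration trial/calibration.json --out trial/
```

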