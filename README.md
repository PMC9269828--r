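# colowave

Microwave colonoscopy polyp detection in R.

A ring-shaped switchable microwave antenna array attached to a colonoscope
tip measures, at every 4 mm step along the colon, the complex transmission
S-parameters of 24 transmitter–receiver pairs at 7.6 GHz. Because
neoplastic tissue has markedly higher dielectric properties than healthy
mucosa (≈30% in relative permittivity, ≈90% in conductivity), a polyp
anywhere on the 360° perimeter — including regions the camera never
displays — perturbs the measured fields. `colowave` turns such frame
sequences into a per-frame polyp alarm, and ships a synthetic trajectory
simulator for building labelled test ensembles where no public raw
recordings exist.

The pipeline has three stages, applied to each frame *n*:

1. **Automatic temporal subtraction calibration.** The most similar
   previous frame is found by the modified Hausdorff distance between the
   frames' S-parameter point sets in the complex plane,
   `MHD(A,B) = max(mean_a min_b |a-b|, mean_b min_a |a-b|)`, and
   subtracted, isolating the scattered field `Es` of any lesion while
   cancelling wall clutter, folds and angulation effects.
2. **Monofocusing reconstruction.** A cross-sectional contrast image
   `I(r) = Σ_i Σ_{j∈{i-1,i,i+1}} Es²(r_Ti, r_Rj) · J₁(2k|r_Rj − r|) ·
   e^{i(2k|r_Rj − r| + φ_ij)}` with `k = 2πf/c` and `φ_ij` the
   transmitter–receiver angular separation; the image maximum `y_n`
   summarises the frame.
3. **Exponential-smoothing outlier detection.** Level
   `s_{n+1} = α·y_n + (1−α)·s_n`, smoothed absolute deviation
   `w_{n+1} = α·|y_n − s_{n+1}| + (1−α)·w_n`, confidence band
   `s ± δ·w`. A frame whose `y_n` lies strictly above the forecast band
   raises the alarm (the "acoustic parking sensor" signal).

Performance is summarised as `sensitivity = 100·TP/(TP+FN)` per lesion and
`specificity = 100·TN/(TN+FP)` per scored healthy frame.

## Worked example

Simulate a 200 mm colon segment with one 30 mm polyp centred at
z = 120 mm, run the pipeline, and evaluate against the ground truth:

```r
library(colowave)

spec <- scene_spec(length_mm = 200,
                   polyps = data.frame(z_center_mm = 120, size_mm = 30),
                   seed = 5)
traj <- simulate_trajectory(spec, label = "demo")
det  <- run_detector(traj, detector_config(alpha = 0.3, delta = 3))
subset(det, alarm, select = c(frame_index, z_mm, y, band_high))
#>    frame_index z_mm       y band_high
#> 5            4   16   106.0     101.3
#> 23          22   88   152.7     114.9
#> 26          25  100   173.5     147.0
#> 27          26  104  6263.6     210.7
#> 28          27  108 18146.8    5902.3

evaluate_ensemble(list(traj))
#>  label histology lesion_size_mm length_mm tp fp tn fn sensitivity specificity
#>   demo     other             30       200  1  2 35  0      100.00       94.59
#> overall (pooled): sensitivity 100.00%, specificity 94.59% (TP=1 FP=2 TN=35 FN=0)
#> overall (macro): sensitivity 100.00%, specificity 94.59%
```

The image maximum `y` jumps by two orders of magnitude as the array enters
the lesion (ground-truth extent 105–135 mm): frames 26–27 exceed their
forecast band and the lesion counts as detected (TP = 1). Two healthy
frames (z = 16, 88 mm) alarm on noise excursions and are counted as false
positives; per-frame specificity is 35/37 = 94.59%.

A command-line interface wrapping the same functions lives at
`system.file("cli", "colowave.R", package = "colowave")` with subcommands
`simulate`, `calibrate`, `reconstruct`, `detect`, `evaluate` and `run`, and
an annotated scene file at
`system.file("extdata", "example_scene.yaml", package = "colowave")`:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "colowave.R", package = "colowave"))')
Rscript $cli simulate --scene scene.yaml --seed 5 --out demo
Rscript $cli detect --in demo.csv --alpha 0.3 --delta 3 --bell --out detections.csv
```

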