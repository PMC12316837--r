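# hotspotmon

Hotspot detection for microwave breast-hyperthermia monitoring.

Microwave hyperthermia heats a breast tumor to 40-45 °C; healthy tissue
must stay below 40 °C. Because tissue dielectric properties drift with
temperature (relative permittivity falls ≈0.25 %/°C, effective
conductivity rises ≈1.25 %/°C), the heating leaves a tiny imprint on the
microwave scattering response of the breast. `hotspotmon` implements a
*direct learning* monitor for this problem, for researchers in
computational microwave imaging and thermal-therapy monitoring:

* a 2-D TM **method-of-moments forward solver** (Richmond
  equivalent-circle cells, complex-argument Hankel functions implemented
  in-package) producing multi-static, multi-frequency scattered fields
  for a synthetic dispersive breast phantom in a lossy coupling medium
  (ε_rb = 20, σ_b = 0.6 S/m, 16 line-source antennas on a 75 mm circle,
  0.5-2 GHz);
* a seeded **random heating-scenario generator** (layered heating
  regions, smooth fields, rise ≤ 24 °C, tumor heated with probability
  0.5) and the **thermo-dielectric coupling**
  Δε_r = −ε_r·0.0025·ΔT, Δσ = σ·0.0125·ΔT (plus an endpoint-anchored
  quadratic family for mismatch studies);
* a convolutional **encoder-decoder** — implemented natively in R,
  including backpropagation — that maps the differential scattered-field
  tensor (real/imaginary channels per frequency, 16×16×32 at full scale)
  directly to the probability image of cells exceeding 40 °C, trained
  with binary cross-entropy, SGD (momentum 0.8, batch 32) and the
  schedule η(t) = 0.01·0.1^(t/v);
* pixel metrics s_acc = (TP+TN)/(TP+TN+FP+FN) and
  s_Dice = 2TP/(2TP+FP+FN), plus the scenario-level **danger accuracy**
  (recall of scenarios with a hotspot outside the tumor);
* a **Born-iterative baseline** estimating the temperature map with
  Tikhonov, truncated-SVD, CGLS or FISTA regularisation, for
  head-to-head comparison with the learned detector.

The methods vignette (`vignettes/hotspot-monitoring.Rmd`) documents the
model, the design decisions and the limits of what the synthetic study
shows.

## Worked example

A minute-scale run of the whole pipeline (24×24 grid, 4 antennas, 2
frequencies, 200 scenarios, 8 epochs):

```r
library(hotspotmon)

cfg <- preset_config("fixture", seed = 42)
cfg$n_samples <- 200L
cfg$epochs <- 8L
res <- run_pipeline(cfg)

print(res$dataset)
print(res$fit)
print(res$eval)
```

```
<hotspot_dataset> 200 scenarios (140/30/30 train/val/test)
  input 4 x 4 x 4, labels 24 x 24, SNR_train 40 dB
  hotspot pixel prevalence 0.230, danger-positive fraction 0.930
<hotspot_cnn> 4x4x4 -> 24x24, 9321 parameters
  8 epochs; final train loss 0.4749, val loss 0.4414, val acc 0.8671
<metrics_report> 30 scenarios
  pixel accuracy  0.8237
  mean s_acc      0.8237
  mean s_Dice     0.3890  (all-negative pairs excluded)
  danger accuracy 1.0000  (28 danger-positive scenarios)
```

Reading the output: the dataset holds 200 simulated heating scenarios
(140/30/30 train/validation/test) with noisy differential scattered
fields as inputs; about a quarter of all pixels are hotspots. After
eight epochs the network classifies 82 % of test pixels correctly — an
untrained all-zeros detector would score the hotspot-free prevalence,
77 % — and every truly dangerous scenario in the small test split is
flagged (danger accuracy 1.0). Desk-scale runs (`preset_config("desk")`:
4 frequencies, 2,000 scenarios, 15 epochs, ~10 min on one CPU) reach
~0.93 pixel accuracy, mean Dice ~0.79 and danger accuracy ~0.97, and
outscore every conventional Born-iterative regulariser on both mean accuracy and Dice.

A command-line wrapper for the same stages (generate-data / train /
evaluate / baseline / sweep) ships in `inst/scripts/hotspotmon.R`.

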