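# srfpet

Automatic measurement of **split renal function (SRF)** from PSMA PET/CT.

PSMA-targeted PET tracers accumulate physiologically in the renal proximal
tubules, so the left/right split of renal uptake tracks split renal
function as measured by dedicated renography. The bottleneck is kidney
segmentation. `srfpet` provides:

* a trainable **3D U-Net** segmenter over the two co-registered channels
  (CT in Hounsfield units, PET in SUV), with same-padding convolutions,
  instance normalization, deep supervision, and class-weighted categorical
  cross-entropy (kidney voxels weight 5, background 1), optimized by
  adaptive moment estimation with Nesterov momentum under a geometric
  learning-rate schedule (5e-5, −1.5% per epoch);
* **largest-connected-component** (26-connected) postprocessing per kidney
  class;
* the **LRF%** statistic
  `LRF% = 100 · Σ SUV(left kidney) / (Σ SUV(left) + Σ SUV(right))`
  plus per-kidney SUV sums and volumes (ml);
* a **synthetic abdominal phantom** simulator (kidney cortex/pelvis
  ellipsoids, bladder, organs, optional distractor lesions, PSF blur,
  noise) with analytically known true LRF%, for desk-scale training and
  validation;
* **multi-reader agreement statistics**: Dice–Sørensen, volume and LRF%
  differences as median (min–max) per source pair, Spearman correlation,
  and Bland–Altman limits of agreement;
* a command-line tool `srf` (simulate / train / segment / measure /
  evaluate).

All volumes are NIfTI (`.nii` / `.nii.gz`); at load everything is
reoriented so that array axis 1 increases toward the patient's left, and
negative PET values are clamped to zero.

## Worked example

Simulate a small cohort, train the desk-scale profile, and measure a
held-out case:

```r
library(srfpet)

cohort <- generate_cohort(6, seed = 42)           # 64^3 phantoms
profile <- train_profile("desk", seed = 42)       # 2-level U-Net, 32^3 patches
model <- train_model(cohort[1:5], profile$net, profile$train)

case <- cohort[[6]]
seg <- predict(model, case$ct, case$pet)
print(seg$result)
print(case$true_lrf_percent)
```

The desk training takes about a quarter of an hour on one CPU; on this
seed the run prints:

```
Split renal function
  LRF%: 42.0
  left : SUV sum 32119.0, volume 43.7 ml
  right: SUV sum 44322.5, volume 59.6 ml
[1] 43.61804
```

i.e. the trained segmenter recovers the phantom's analytic ground truth
(LRF% 43.6) to within 1.6 percentage points on this held-out case, and
reports the per-kidney summed SUV and segmented volumes it used. Reader-style
agreement reports come from `evaluate_sources()` +
`summarize_agreement()`, or from the CLI:

```sh
inst/exec/srf simulate -n 8 --seed 7 -o cohort/
inst/exec/srf evaluate --cohort cohort/ -o report/ --seed 7
```

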