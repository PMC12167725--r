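---
title: "Measuring split renal function from PSMA PET/CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring split renal function from PSMA PET/CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

PSMA-targeted PET tracers accumulate physiologically in the renal proximal
tubules, so the left/right split of renal tracer uptake tracks split renal
function (SRF) as measured by dedicated renography. The statistic of
interest is the left renal function percentage,

$$\mathrm{LRF\%} = 100 \cdot
  \frac{\sum_{v \in \text{left kidney}} \mathrm{SUV}_v}
       {\sum_{v \in \text{left}} \mathrm{SUV}_v +
        \sum_{v \in \text{right}} \mathrm{SUV}_v},$$

which requires a voxel-accurate segmentation of both kidneys in the PET
volume. Manual segmentation is the bottleneck; `srfpet` automates it with
a 3D U-Net over the co-registered CT and SUV channels and then measures
LRF%, per-kidney SUV sums, and per-kidney volumes.

Everything operates in a fixed anatomical axis convention established at
the I/O boundary: array axis 1 increases toward the patient's *left*
("LAS" in NIfTI orientation terms). "Left kidney" (label 1) therefore
always means anatomical left, and the convention makes the left/right
semantics of every downstream rule testable. Negative PET voxels (possible
reconstruction artifacts) are clamped to zero at load, since SUV is
non-negative by definition.

## Segmentation model

The segmenter follows the classic volumetric U-Net design: per resolution
level two 3x3x3 same-padding convolutions (channel counts doubling per
level), each followed by instance normalization and a leaky rectifier;
2x2x2 max-pooling down; 2x2x2 transposed convolutions up; skip
connections by channel concatenation; and a 1x1x1 head emitting
unnormalized scores for three classes (background, left kidney, right
kidney). The rectifier's small negative-side slope (0.1, configurable) is
deliberate: on short schedules a hard rectifier admits a degenerate
optimum in which whole feature maps are silenced over entire structures —
the head then classifies "kidney" by its bias wherever features are dead,
which segments kidneys yet destroys the contextual information needed to
tell left from right. The leak makes that solution unavailable. Scores are kept unnormalized in the model output; the softmax
lives inside the loss and the inference argmax, which is the numerically
stable place for it.

Design points that were genuinely open and how they were fixed:

* **Normalization layer.** Instance normalization (per sample, per
  channel) rather than batch normalization: desk-scale batches are small
  and patch statistics differ strongly between foreground-biased and
  background patches.
* **Input scaling.** The two raw channels live on very different numeric
  scales (HU in the hundreds, SUV in the tens). A fixed affine rescale
  (HU/100, SUV/10) is applied inside the forward pass, on by default and
  exposed in `network_config()`. No per-volume statistics are used, so
  the quantitative meaning of SUV is untouched.
* **Decision rule.** Per-voxel argmax with ties broken toward the lowest
  class index, i.e. background-conservative and deterministic.

### Loss

Training minimizes class-weighted categorical cross-entropy: each voxel is
weighted by the weight of its *true* class, background 1 and each kidney
class 5, countering the extreme class imbalance of torso volumes. The
per-patch loss is the weighted *mean* (sum divided by total weight), which
keeps magnitudes comparable across patch sizes. Deep supervision attaches
the same loss to every decoder scale (labels downsampled by nearest
neighbour, low-index corner representative per 2x2x2 block); scale weights
halve per scale, finest first, and are normalized to sum to one.

### Training recipe

The optimizer is adaptive moment estimation with Nesterov momentum
(moment decays 0.9/0.999, epsilon 1e-8 — the published defaults). The
learning rate starts at 5e-5 and is multiplied by 0.985 after each epoch
(constant within an epoch). The full-size profile trains 160^3-voxel
patches for 100 epochs of 10,000 random patch samples; "random samples"
is interpreted as *patches*, drawn with a 50% foreground bias (patch
centred on a uniformly drawn kidney voxel when any exist), because purely
uniform patch sampling of torso volumes would starve kidney voxels despite
the 5x class weight. Batch size is unconstrained by the recipe; 2 is used
at full size (memory-plausible for 160^3) and 8 at desk scale.

Each sampled (CT, PET, label) triple passes through the paired
augmentation: one affine transform (isotropic scale 0.9–1.1, per-axis
rotation within ±10°, shear within ±0.05, translation within ±10 mm,
each applied with probability 0.5, drawn once and applied identically to
all three patches — trilinear for the image channels, nearest neighbour
for labels), plus CT-only intensity perturbations (HU shift ±50, HU scale
0.9–1.1, Gaussian smoothing sigma up to 1.5 mm, additive noise SD up to
20 HU). SUV intensities are *not* perturbed by default: LRF% is a ratio
of SUV sums, and corrupting the quantity being delineated would work
against the measurement; a flag exists for PET noise. Out-of-field voxels
created by the affine are filled with ambient values (CT −100 HU, PET 0,
labels 0).

### Desk profile and problem sizes

All shipped experiments use the *desk* profile: 64^3 phantom volumes at
the scanner spacing (2.73 × 2.73 × 2.79 mm), 32^3 patches, a 2-level
U-Net with 8 base channels, 20 epochs of 200 samples. These sizes make
the full simulate–train–evaluate loop a desk-scale experiment (minutes,
one CPU) while exercising every component the full-size profile uses; the
`paper` profile (160^3 patches, 4 levels, 16 base channels,
100 × 10,000 samples, batch 2, learning rate 5e-5) is the same code path.

Two desk-profile choices deserve their rationale. The full recipe takes
roughly 500,000 optimizer steps; the desk schedule allows at most 4,000
(200 samples × 20 epochs at batch 1). How far adaptive moment estimation
can travel from initialization is bounded by the cumulative
learning-rate mass `lr0 · Σ (1 − 0.015)^e · steps_per_epoch`: about 12.9
for the full recipe but only 0.17 for the desk schedule at 5e-5 — and
empirically a desk run at 5e-5 never moves the argmax off background
(kidney-vs-background score margins shift by ~0.2 over the entire
schedule). The desk profile therefore uses batch 1 (maximizing steps at
fixed sample count) and an initial learning rate of 2e-3, chosen so the
cumulative mass (~6.9) approaches the full recipe's; the schedule shape
(−1.5% per epoch) is untouched. Relatedly, the scoring
heads are zero-initialized: initial class scores are exactly tied
(argmax falls to background via the tie rule) and the short schedule
spends its movement budget on signal rather than on cancelling
initialization noise.

## Inference and measurement

Whole volumes are scored by overlapping-patch inference at 50% stride
with mean fusion of scores in overlaps, after resampling both channels to
the model grid. After argmax, only the largest 26-connected component
(face + edge + corner adjacency) of each kidney class is kept — the
postprocessing that removes stray distant false positives such as avid
lymph-node metastases. An exact size tie keeps the component whose
smallest linear voxel index is smallest (deterministic). A kept component
smaller than 10 ml is flagged in the result metadata as likely spurious
but is *not* removed: the threshold only surfaces the known failure mode.

The cleaned labels are mapped back to the native PET grid by nearest
neighbour and LRF% is computed from native-grid SUV values, so no
interpolated SUV enters the sums. (On the 2.73-mm model grid the
difference is negligible, but the choice is fixed and documented.)

## Synthetic phantom

Because clinical data cannot ship with the package, a phantom simulator
provides paired CT/PET volumes with analytically known truth. Each
phantom paints piecewise-constant fields: faint soft-tissue background
(SUV 1, HU 40); a large high-uptake liver sphere (SUV 12, HU 60) abutting
the right kidney's upper pole — the tracer is hepatically cleared, so
intense liver uptake is characteristic — and a smaller moderate-uptake
spleen (SUV 6, HU 45) by the left kidney; ellipsoidal kidneys with a hot
cortex shell (SUV 25) around a low-uptake pelvis core (SUV 5, inner
ellipsoid at 55% of the semi-axes); an intensely hot bladder (SUV 60);
and optional para-aortic distractor lesions (SUV 10–30) that emulate the
lymph-node failure mode. The adjacent organs matter beyond realism: they
are the *local* evidence of laterality. A translation-equivariant
segmenter can only tell the left kidney from the right through nearby
context within its receptive field, exactly as radiologists' local
landmarks (liver vs spleen) do; a phantom without them would make
left/right assignment undecidable in principle for any such model. The PET field is
then blurred by a Gaussian point-spread function (default FWHM 5 mm),
Gaussian noise is added (default SD 1 SUV), and negatives are clamped; the
CT field receives its own noise (SD 15 HU) but no PSF blur, which is a
PET phenomenon. The uptake palette is plausibility-driven — chosen to
mimic the qualitative contrast of PSMA-ligand images (intense renal cortex
and bladder) — not fitted to any dataset, and every value is
config-overridable.

The *true* LRF% of a phantom is defined on the pre-blur, pre-noise SUV
field restricted to the rasterized kidney ellipsoids. That makes it an
exact recovery target: blur and noise effects appear as measurable biases
rather than as ambiguity in the truth.

Cohorts draw per-case kidney size (±25% on the semi-axes), uptake (±50%),
and position jitter, in a variant mix whose default follows the hard-case
composition the segmenter is designed around: mostly two normal kidneys
plus minorities of solitary (one kidney absent), hypoplastic (half-size),
symmetric-low-uptake, and asymmetric-low-uptake cases (fractions 120, 6,
5, 1 and 4 out of 136). Variant counts are largest-remainder-rounded
fractions of n, shuffled across case indices. Anatomy scales with the
field of view so small desk grids remain collision-free; a voxelized
disjointness check rejects any spec whose bladder, lesions, or kidneys
overlap.

Simulated readers perturb the truth mask per kidney independently by a
boundary shift drawn uniformly in ±magnitude voxels: whole steps as
26-connected dilation/erosion, the fractional remainder as a random
subset of the next boundary shell. The fractional part matters: at
2.73-mm voxels a full one-voxel shift of an entire kidney shell moves far
more SUV than careful human readers disagree by, so sub-voxel shifts are
what "reader-like" perturbations look like on this grid.

### What the phantom does and does not emulate

The phantom reproduces the statistical structure the pipeline assumes —
dual-channel contrast, cortical uptake concentration, hot confounders,
PSF blur, additive noise, anatomical variants — but not projection
physics (no sinograms or iterative reconstruction), attenuation,
respiratory motion, or textured organ interiors. Passing the phantom
experiments therefore demonstrates that the implementation learns and
measures correctly under known conditions; it does not certify clinical
accuracy on scanner data, which requires clinical evaluation.

## Agreement statistics

Segmentation sources (readers, models, truth) are compared pairwise per
case: Dice–Sørensen coefficient and volume difference per kidney, and the
LRF% difference per case, every difference oriented as first minus second
source (model-vs-reader reported as model − reader). Two empty masks have
Dice 1 by convention — the correct convention for solitary-kidney cases
where both sources rightly segment nothing on one side; exactly one empty
mask gives 0. Reports give median (min–max) per source pair with ordered
records collapsed to one row per unordered pair, Spearman rank
correlations (average ranks on ties; zero rank variance is an error, not
an NA) across sources for LRF% and renal volumes, and Bland–Altman
analysis of LRF%: bias = mean difference, limits of agreement =
bias ± 1.96 SD with the n−1 denominator. Absent kidneys contribute no
volume observations to the volume correlations.

## Numerical choices

* Convolution arithmetic runs in single precision (the gemm-friendly
  choice; training never needs more); losses, statistics, and all
  measurement reductions are double precision. Gradients are verified
  against finite differences in the test suite.
* Instance norm uses eps 1e-5. He-scaled Gaussian initialization, zero
  biases, unit gains; all draws run through R's RNG under explicit seeds,
  so builds, cohorts, and training histories are bit-reproducible on a
  fixed platform (BLAS reduction order can in principle vary across
  platforms; within one platform runs are identical).
* Resampling uses the voxel-edge-aligned mapping
  `in = (out + 0.5) * ratio − 0.5`, which makes resampling at the input
  spacing an exact identity; images interpolate trilinearly, labels by
  nearest neighbour (the only label-safe choice); out-of-range
  coordinates clamp to the edge (constant extension), so degenerate
  single-voxel axes upsample to constants rather than erroring.
* Gaussian blurs are separable with mirror boundaries, kernels truncated
  at 3 sigma and renormalized.
* Whether the original pipeline normalized PET intensities before the
  network is unknown; this implementation feeds raw (affinely rescaled)
  SUV and documents the ambiguity rather than hiding a normalization.

## Known limitations

* The desk schedule's 4,000 optimizer steps leave visible run-to-run
  variance: different cohort/training seeds can shift held-out median
  Dice by several points and worst-case LRF% errors by a few percentage
  points. The full-size recipe's 500,000 steps wash this out; at desk
  scale it is the price of a minutes-long experiment.

* The phantom's uptake values are plausible, not calibrated; absolute
  DSC/LRF numbers from phantom experiments should be read as
  software-correctness evidence, not clinical performance.
* The desk profile's 2-level network is intentionally small; markedly
  asymmetric or unusual anatomy (horseshoe kidney) is out of its
  training distribution, exactly as it is for the full-size model.
* `simulate_reader` models boundary-shift disagreement only, not
  systematic protocol differences between readers.
* SRF from PET uptake does not replace absolute function measures such as
  glomerular filtration rate; the package measures the split, nothing
  more.
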