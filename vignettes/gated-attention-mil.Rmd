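---
title: "Gated-attention MIL for sacroiliitis MRI: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated-attention MIL for sacroiliitis MRI: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the model and its
assumptions, what the synthetic phantom does and does not emulate, the
numerical choices, and the places where the design was genuinely open and a
choice had to be made.

## The problem and the weak-supervision assumption

Active sacroiliitis shows on fat-suppressed T2 MRI as focal, patchy bone
marrow edema (BME): bright subchondral signal confined to a minority of the
25–60 axial slices in a study. Diagnostic labels exist per patient, not per
slice. Multiple instance learning matches this structure exactly: a patient
is a *bag* of slice *instances*, the bag label is positive when at least some
slices carry evidence, and the model must learn *which* slices matter without
ever being told.

The working assumptions are: (i) evidence is slice-sparse — most slices of a
positive patient are unremarkable; (ii) evidence is local within a slice
(focal hyperintensity near the joints); (iii) slices within a bag are
exchangeable for classification — the model is deliberately permutation
invariant, and the test suite asserts it.

## Model

Per slice, a convolutional backbone produces an L-dimensional instance
feature $h_k$. Gated attention scores each slice through two branches — a
tanh branch for signed evidence and a sigmoid *gate* that can switch a slice
off — combined elementwise:

$$a_k = \frac{\exp\{w^\top(\tanh(V h_k) \odot \sigma(U h_k))\}}
             {\sum_j \exp\{w^\top(\tanh(V h_j) \odot \sigma(U h_j))\}}.$$

The bag embedding $z = \sum_k a_k h_k$ goes through one affine layer to two
classes with softmax. The published configuration pairs this pooling with an
ImageNet-pretrained ResNet-18 ($L = 512$, attention dimension $D = 128$, one
attention branch, dropout 0.5). This package has no deep-learning runtime to
load pretrained weights into, so it ships a compact backbone (`small_cnn`)
with the whole forward/backward machinery written in R and gradient-checked
against central finite differences; the attention, aggregation, and
classification stages are exactly the published form.

### The compact backbone

Three conv blocks (3×3 convolution, instance normalization, ReLU, 2×2 average
pooling), then global **max** pooling and a linear projection to $L = 64$
(defaults: channels 8/16/32, $D = 32$). Two choices deserve justification
because a first implementation without them demonstrably fails:

- **Instance normalization.** Every slice shares the same gross anatomy, so
  raw activations are dominated by a large constant background component.
  Normalizing each channel per slice removes it, which multiplies the
  relative strength of the lesion signal in the pooled features.
- **Global max pooling, not average pooling.** A focal lesion occupies
  roughly 1% of a slice's pixels. Average pooling attenuates its feature
  response by that area fraction; measured on untrained backbones, the
  lesion-versus-healthy instance-feature gap is ~2% of the feature scale
  under average pooling and ~8 within-class standard deviations under max
  pooling. With average pooling, the class signal is so small that the bag
  classifier's logit spread grows quadratically slowly and a short training
  budget cannot calibrate it; with max pooling the same budget converges.
  Focal hyperintensities are local maxima — max pooling is the matching
  inductive bias.

The classification head is zero-initialized, so an untrained model outputs
exactly (0.5, 0.5) and the first-epoch loss on uninformative data sits at
$\ln 2$ — a property the test suite uses as a training sanity check.

## Preprocessing

Slices are standardized in a fixed order: bilinear resize to the working
resolution, min–max rescale to [0, 255] (a constant slice passes through
unchanged), then global 256-bin histogram equalization with the mapping
$v \mapsto \lfloor 255\,\mathrm{cdf}(v)\rfloor$; whether to equalize before
or after the rescale was unspecified upstream, and rescale→equalize is fixed
here and asserted idempotent to within one gray level. Grayscale is
replicated to three channels and normalized with the ImageNet statistics
(means 0.485/0.456/0.406, sds 0.229/0.224/0.225), keeping compatibility with
pretrained backbones. Train-time augmentation mirrors slices horizontally
and vertically with probability 0.5 each and jitters brightness and contrast
by up to ±20% (factors drawn uniformly; applied on the [0, 1] scale with
clipping), independently per slice. Test-time augmentation is deterministic:
identity plus horizontal flip, class probabilities averaged — probability
averaging is the bounded, standard reading of "averaging the outputs", and a
logit-averaging variant is available behind a config switch.

## Training protocol

Defaults follow the published table: Adam, learning rate $10^{-4}$, weight
decay $10^{-3}$, batches of four patient-level bags, 20 epochs, cross-entropy
loss, model selection by the highest validation F1 (threshold 0.5; ties to
the earliest epoch). Bags have variable sizes, so a "batch" is gradient
accumulation over four bags processed singly — mathematically identical to a
padded batch, without the padding. Dropout is applied to the bag embedding
$z$ (the location was unspecified upstream). Validation is computed without
TTA, reading TTA strictly as an inference-time strategy. Training aborts if
any subject id appears in both the training and validation sets; the split
construction itself is patient-wise by design. Everything — shuffling,
dropout, augmentation, initialization — is driven by one seed, and two runs
with the same seed are bit-identical.

## The synthetic phantom

The generator emulates exactly the statistical structure the analysis
assumes, and no more:

- **Anatomy.** A smooth wide intensity ramp (25–185 in 8-bit units) with two
  symmetric bright ellipses for the sacroiliac joint regions. The ramp is
  deliberate: global histogram equalization preserves local lesion contrast
  only where intermediate intensities carry histogram mass, as they do on
  real T2 slices. A flat two-tone background would let equalization crush an
  80-unit planted contrast to ~12 gray levels and silently destroy the
  planted signal.
- **Lesions.** In positive bags, a contiguous run of
  $\lceil f \cdot n_\text{slices}\rceil$ slices (f uniform in [0.10, 0.30] by
  default — sparse, axially continuous involvement, as BME spans neighboring
  slices) receives one bright blob centered inside a joint ellipse: a flat
  core of radius `lesion_radius_px` with a Gaussian skirt (σ = radius/2).
  The flat core makes the *mean* elevation inside the nominal lesion disc
  equal `lesion_contrast` exactly, which is the contract the generator tests
  verify directly from the emitted pixels. Default contrast 80 over noise
  sd 10 (8 σ) is the clearly-separable regime the end-to-end tests assume.
- **Determinism.** Each subject draws from a derived stream (cohort seed +
  subject index), so regenerating or extending a cohort never reshuffles
  existing subjects; cohorts are byte-identical across runs.

It does **not** emulate scanner physics, coil inhomogeneity, anatomical
variation between subjects, erosions or structural lesions, or multi-sequence
appearance. Passing the end-to-end tests therefore demonstrates that the
pipeline's machinery — optimization, attention, evaluation — works as
specified on data with the assumed structure; it says nothing about clinical
performance on real MRI.

## The reduced end-to-end experiment

The test suite trains the full pipeline at a CPU-scale problem size: 70 bags
(40 train / 10 val / 20 test, balanced), 25–30 slices per bag, 64×64 px
phantoms with lesion radius 4 px (the 224-px default radius of 12 px, scaled
proportionally), 5 epochs. Two settings differ from the published protocol,
as experiment design under a fixed 50-optimizer-step budget, and are worth
recording:

- **Learning rate 3×10⁻³.** The published 10⁻⁴ is a fine-tuning rate for a
  pretrained backbone; training the compact backbone from scratch in 50 steps
  needs a larger step. At 10⁻³ the classifier converges but the attention
  distribution has not yet concentrated by epoch 5; 3×10⁻³ is the smallest
  rate tried at which both the classifier and the attention reach their
  asymptotic behavior inside the budget.
- **Dropout 0.25.** With dropout 0.5 on the compact 64-dimensional
  max-pooled embedding, the few coordinates carrying lesion evidence are
  dropped half the time, which biases the head toward "positive" and can
  leave negatives uncalibrated at p ≈ 0.5 within the step budget. The
  published 0.5 is calibrated to a 512-dimensional embedding with distributed
  evidence; 0.25 is used at this scale and 0.5 remains the package default.

Under this protocol the suite requires held-out accuracy ≥ 0.90 and mean
attention mass on planted lesion slices ≥ 2× the uniform baseline
$|\text{lesion}|/K$. Across development seeds the accuracy criterion passes
with a wide margin; the attention-mass ratio is the more variable statistic
(roughly 2–5× across seeds), which is the honest reading of how quickly
gated attention concentrates in 5 epochs.

## Evaluation statistics

Patient-level metrics come from the confusion matrix (positive = inflamed);
any metric with a zero denominator is reported as `NA`, never as zero. The
AUC is the Mann–Whitney probability that a random positive outscores a
random negative with ties at ½, computed from mid-ranks and cross-checked in
the tests against exhaustive pair counting, the trapezoidal ROC integral,
and pROC. The AUC standard error uses the Hanley–McNeil closed form; its
adequacy test reports $Z = (A - 0.5)/SE$ and one-sided normal power at
$\alpha$. At the published operating point (A = 0.9468, 42/43 subjects) the
closed form gives SE ≈ 0.0256 and power indistinguishable from 1. Percentage
-point comparisons between two models are reported unrounded with a 2-decimal
display column.

## Interpretability

`rank_slices()` orders slices by attention (ties to the lower index; top-5 by
default, mirroring how such rankings are usually displayed). `grad_cam()`
differentiates the *bag-level* logit of the target class through the
attention-weighted path back to the backbone's last convolutional maps of the
chosen slice: channel-averaged gradients weight the maps, the weighted sum is
rectified, bilinearly upsampled, and min–max normalized; a constant map is
defined as all zeros, and raw logits (not softmax) make the map invariant to
constant logit shifts. Back-propagating through the attention path (rather
than a per-slice logit) captures both the slice's direct feature contribution
and its influence on the attention distribution. On synthetic cohorts,
`attention_lesion_overlap()` turns interpretability into a measurable
quantity — attention mass on planted lesion slices and precision-at-k against
the uniform baseline — which is what the tests assert; with real radiologist
annotations the same comparison would be qualitative.

## Numerical choices and degenerate inputs

Softmaxes subtract the maximum before exponentiation. Cross-entropy clamps
the true-class probability at $10^{-12}$. Histogram equalization of a
single-valued image, and min–max rescaling of a constant image, are defined
as the identity. Attention over a single-slice bag is exactly [1]. Empty
folders, missing labels, duplicate subject ids, infeasible split counts, and
train/validation subject overlap are hard errors, not warnings. JSON
checkpoints round-trip parameters at full double precision.

## Known limitations

- The compact backbone is not a pretrained ResNet-18; absolute performance
  on real MRI is out of scope, and no clinical claim is made.
- The phantom's anatomy is procedural; domain shift, scanner variation, and
  structural (non-edema) lesions are not modeled.
- Only binary patient labels are supported — no severity grading or
  slice-level annotations.
- The baseline comparator averages slice probabilities; a logit-averaging
  variant exists mainly because an affine head commutes with averaging at
  the logit level, which is what makes the uniform-attention equivalence
  test exact.
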