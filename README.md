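# milsij

Gated-attention multiple instance learning (MIL) for patient-level
classification of sacroiliac-joint MRI slice stacks as **active sacroiliitis**
versus **healthy**.

Active sacroiliitis — the imaging hallmark of early axial spondyloarthritis —
appears on fat-suppressed T2 MRI as focal bone marrow edema that affects only
a handful of the 25–60 axial slices acquired per patient. Labels, however,
exist only at the patient level. `milsij` treats each patient as a *bag* of
slice *instances*: a convolutional backbone embeds every slice, a gated
attention module scores how informative each slice is, and the
attention-weighted bag embedding is classified. The attention weights double
as a slice-level explanation, and Grad-CAM maps localize the evidence within
a slice. The package is aimed at medical-imaging researchers who want a
self-contained, CPU-scale, fully testable implementation of this pipeline —
including a synthetic cohort generator, so every component can be exercised
without any clinical data.

## The model

For patient *i* with slices x<sub>i1</sub>, …, x<sub>iK</sub>, the backbone
f(·) produces instance features h<sub>ik</sub> = f(x<sub>ik</sub>) ∈ R<sup>L</sup>.
Gated attention scores each slice with a tanh branch multiplied elementwise
by a sigmoid gate,

&nbsp;&nbsp;&nbsp;&nbsp;a<sub>k</sub> = softmax<sub>k</sub>{ wᵀ( tanh(V h<sub>k</sub>) ⊙ σ(U h<sub>k</sub>) ) },

and the bag embedding z<sub>i</sub> = Σ<sub>k</sub> a<sub>k</sub> h<sub>ik</sub>
is passed through an affine two-class head with softmax. Training uses
cross-entropy on bag labels with Adam, gradient accumulation over patient
bags, and model selection by the best validation F1. At inference,
deterministic test-time augmentation (TTA) runs each bag in original and
horizontally flipped form and averages the class outputs. Evaluation covers
confusion-matrix metrics, ROC/AUC (Mann–Whitney, ties at ½), the
Hanley–McNeil AUC standard error

&nbsp;&nbsp;&nbsp;&nbsp;SE² = [A(1−A) + (n₊−1)(Q₁−A²) + (n₋−1)(Q₂−A²)] / (n₊ n₋),
&nbsp;&nbsp;Q₁ = A/(2−A), Q₂ = 2A²/(1+A),

and the one-sided power of the AUC test against a null of 0.5.

All neural-network numerics (im2col convolution, instance normalization,
gated attention, Adam, backpropagation) are implemented in base R and are
gradient-checked against finite differences in the test suite. The compact
`small_cnn` backbone (three conv blocks → global max pooling → linear
projection) trains in minutes on one CPU.

## Worked example

Generate a small synthetic cohort, assemble a bag, and run the model:

```r
library(milsij)

cfg <- cohort_config(n_positive = 3, n_negative = 3, slices_min = 25,
                     slices_max = 30, image_size = 64, lesion_radius_px = 4,
                     seed = 7)
cohort_dir <- file.path(tempdir(), "demo_cohort")
manifest <- generate_cohort(cfg, cohort_dir)
manifest <- split_patients(manifest,
                           list(train = c(2, 2), val = c(0, 0), test = c(1, 1)),
                           seed = 7)
head(manifest, 3)
#>   subject_id    label split n_slices                               path
#> 1     pos001 positive  test       26 /tmp/.../demo_cohort/pos001
#> 2     pos002 positive train       29 /tmp/.../demo_cohort/pos002
#> 3     pos003 positive train       25 /tmp/.../demo_cohort/pos003

bag <- assemble_bag(manifest$path[1], label = manifest$label[1], image_size = 64)
bag
#> <mil_bag> subject pos001, label positive, 26 slices of 64x64

model <- mil_model(model_config(dropout_rate = 0.25), seed = 1)
pred <- forward(model, bag)
pred
#> <bag_prediction> pos001: P(positive) = 0.5000 -> negative
round(head(pred$attention$a, 5), 4)
#> [1] 0.0355 0.0369 0.0374 0.0384 0.0362
```

An untrained model sits exactly at chance (the head is zero-initialized) with
near-uniform attention; `train_mil()` fits it — see
`vignette("gated-attention-mil")` for the full training walk-through and the
reduced end-to-end experiment the test suite runs.

The evaluation utilities work on any patient-level confusion matrix or
score table:

```r
m <- metrics_from_cm(confusion_matrix(tp = 39, fn = 3, tn = 34, fp = 9))
str(m)
#> List of 5
#>  $ accuracy   : num 0.859
#>  $ sensitivity: num 0.929
#>  $ specificity: num 0.791
#>  $ precision  : num 0.812
#>  $ f1         : num 0.867

auc_power(auc = 0.9468, n_pos = 42, n_neg = 43, alpha = 0.05)
#> $z
#> [1] 17.45338
#> $se
#> [1] 0.02559963
#> $power
#> [1] 1
```

So a test cohort of 42 inflamed / 43 healthy subjects at AUC 0.9468 carries
an AUC standard error of ≈ 0.026 and essentially unit power against the
no-discrimination null — the cohort size is statistically adequate.

A thin command-line wrapper with `generate` / `train` / `evaluate` /
`explain` subcommands lives at `inst/cli/milsij.R` (driven by a YAML config;
see `?read_pipeline_config`).

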