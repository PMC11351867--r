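---
title: "A quality-gated interactive segmentation cascade: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quality-gated interactive segmentation cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Automatic lesion segmentation of multiparametric MR slices is accurate on
easy cases and unreliable on hard ones; fully interactive promptable models
are accurate everywhere but demand a user interaction for every image.
`icseg` implements the intermediate regime: spend human effort only where an
automatic result is predicted to be poor.

For a slice $x_i \in \mathbb{R}^{3\times H\times W}$ (T2W-, ADC- and
high-b-value-DWI-like channels) the cascade is

1. **Coarse segmentation** $p^c_i = \theta_C(x_i)$: an encoder–decoder
   network with five encoder blocks and four max-poolings (deepest stride
   16), squeeze-and-excitation recalibration after every block and
   non-local self-attention on the two deepest skip connections, trained
   with the soft Dice loss.
2. **Quality regression** $s_i = \theta_R(\mathrm{cat}(f^{final}_i, p^c_i))$:
   a convolutional regressor over the concatenation of the coarse model's
   final-stage feature map and its two-channel probability map, trained with
   mean squared error against $d_i$, the Dice coefficient of the binarized
   coarse mask against ground truth. Output is linear during training and
   clamped to $[0,1]$ at inference.
3. **Gate**: slices with $s_i < t$ are routed to *manual* box prompts
   (simulated by expanding ground-truth boxes, the reproducible stand-in for
   a user); slices with $s_i \ge t$ get boxes derived from the connected
   components of the coarse mask. All boxes are expanded by 40% in width and
   height.
4. **Fine segmentation** $p^f_i = \theta_F(x_i, \mathrm{bbox}(p^c_i \mid s_i))$:
   a prompt-conditioned network consuming the three image channels plus a
   rendered box-interior channel, trained with cross-entropy plus Dice loss
   on boxes randomly extended by 0–60% and jittered by up to 20 px.

The trade-off between workload and accuracy is traced by
`sweep_thresholds()`: the *rejection ratio* (fraction of slices routed to
manual interaction) is a non-decreasing step function of $t$, and mean final
Dice rises with it.

## Evaluation machinery

* **Dice** $2|P\cap G|/(|P|+|G|)$, with both-empty pairs scored 1 and
  one-empty pairs 0. The both-empty convention rewards correct negatives at
  image level; it also means cohort-mean Dice includes lesion-free slices.
* **95% Hausdorff distance**: boundary pixels are mask pixels with a
  4-neighbour outside the mask; directed nearest-boundary distances are
  computed both ways in physical units by an exact separable Euclidean
  distance transform (anisotropic spacing supported), pooled, and summarized
  by the 95th percentile with linear interpolation. Pooling the two directed
  sets makes the statistic symmetric; the published formula brackets both
  directed sets together and contains an index slip in its second set, so
  the standard symmetric reading is implemented. Pairs with an empty mask
  are undefined: they are excluded from aggregates and counted.
* **Lesion-level detection**: lesions are 26-connected 3D components. A
  ground-truth component is detected when the fraction of it covered by the
  prediction reaches $\tau = 0.1$; predicted components are scored
  symmetrically for precision; F1 is the harmonic mean. The low $\tau$
  reflects large inter-observer variability in lesion extent. Volumes
  without ground-truth (or predicted) components contribute no recall (or
  precision) denominators; counts pool across patients.
* **$R^2$** of the quality regression per its defining identity, and the
  rejection ratio with a strict below-threshold count (a score exactly at
  $t$ stays automatic).

## The phantom generator

Real mpMRI cohorts cannot ship with the package, so all training and
testing run on a seeded phantom emulating their decisive features: an
elliptical gland with smooth low-frequency texture; 0–3 lesions per patient
drawn as ellipses warped by low-frequency radial perturbations (irregular
shapes, ambiguous boundaries after light smoothing); channel-specific lesion
contrast (dark in the ADC-like channel, bright in the DWI-like channel, mildly
dark in the T2W-like channel); additive Gaussian noise; lesions spanning 1–4
contiguous slices of an 8-slice patient volume so 3D lesion metrics are
meaningful. Splits are assigned per patient.

The `difficulty` knob scales lesion contrast-to-noise down as it rises and
is drawn stratified per patient (not per slice) over $[0,1]$: the rejection
network must learn quality variation *across* patients. Three choices
deserve emphasis:

* **Contrast floor.** At `difficulty = 1` a lesion retains 10% of its
  nominal contrast rather than vanishing. A lesion with exactly zero
  contrast is unrecoverable *and unassessable* — no observer could tell a
  missed lesion from a lesion-free slice, so the quality target would be
  independent of the input and quality regression would have an irreducible
  error ceiling. Faint-but-present is also the realistic regime: lesions
  that defeat automatic segmenters are still visible to radiologists.
* **Difficulty is globally visible.** Difficulty raises the noise standard
  deviation (by up to 4× at `difficulty = 1`,
  `noise_difficulty_gain = 3`) as well as lowering lesion contrast.
  If difficulty acted on lesion contrast alone, it would leave no trace on
  a slice whose lesion the coarse network missed — quality would again be
  unpredictable exactly where prediction matters. Hard cases in real
  cohorts are hard *globally* (noise, motion, poor tissue contrast), so
  every slice of a difficult patient carries evidence of its difficulty.
  Contrast-to-noise still decreases strictly with difficulty.
* **What the phantom does not model**: anatomy (zonal structure), MR
  physics, bias fields, inter-sequence misregistration, annotation
  variability. Passing tests on phantoms therefore demonstrates that the
  cascade's machinery — training, gating, box logic, metrics — behaves as
  designed, not that the shipped desk-scale networks would segment clinical
  data.

## Desk-scale profiles and numerical choices

All three networks train on one CPU. The profiles used throughout the test
suite and the acceptance script are: 64×64 slices, 40 patients × 8 slices,
base width 8 for the coarse and prompt networks (channel cap 8× base), a
four-stage backbone with the prescribed (1024, 512, 1) regression head for
the rejection network, batch size 4, and 14–30 epochs per stage (the
rejection regressor is by far the cheapest per step and takes the most
epochs). A full-scale profile (256×256, base width 64, large pretrained
backbone) is a configuration change, not a code change.

The rejection backbone's global pooling is *multiscale*: per-channel mean
and maximum are pooled after every convolutional stage and concatenated
into the regression head. With tens of training patients, a deep backbone
that only pools its final stage memorizes patient-specific spatial detail
instead of the global statistics (peak confidence, activation roughness,
mask fragmentation) that actually predict segmentation quality; pooling
every stage restricts the hypothesis space to such statistics and made the
difference between chance-level and useful held-out regression in
development.

Numerical decisions, each visible as a default with a rationale:

* **Dice smoothing**: the evaluation-form `dice_loss()` uses
  $\varepsilon = 10^{-5}$, which only guards the 0/0 of empty pairs. The
  *training* loss uses $\varepsilon = 1$ (`dice_eps`): with a tiny
  $\varepsilon$ a lesion-free slice can never reach zero loss (the softmax
  foreground mass cannot fall below $\varepsilon$), so half the training set
  would permanently push every pixel toward background; with
  $\varepsilon = 1$ the empty-slice optimum is attainable and training is
  stable. Lesion-free slices are kept in coarse training.
* **Batch normalization** (with running statistics at inference) after
  every convolution of the encoder–decoder nets: without a normalization
  layer, Dice-loss training of a from-scratch U-Net collapses to the
  all-background local optimum. Batch — not instance — normalization is the
  deliberate choice: instance normalization erases per-sample amplitude
  deviations, and with it every trace of image quality from the final-stage
  feature map, which is precisely what the downstream rejection network
  must read (swapping instance for batch normalization moved held-out
  quality-regression R² from ~0.4 to ~0.85 in development). The rejection
  backbone itself has *no* normalization for the same reason.
* **Optimizers**: Adam for coarse and rejection with polynomial decay
  (exponent 0.9, rate exactly 0 at the final step); AdamW
  ($\beta_1=0.9, \beta_2=0.999$, weight decay 0.01) for the prompt network.
  Desk-scale learning rates are 3e-3 (coarse; from-scratch training with
  normalization tolerates and needs more than the classic 1e-3) and
  3e-3 (rejection, both parameter groups, since nothing is pretrained; a
  pretrained backbone would use 1e-4). The rejection trainer adds dihedral
  augmentation of its input maps (the target is invariant) and weight decay
  1e-3 against the wide head's overfitting.
* **SE reduction ratio 8**; non-local attention only on the two deepest
  skips (quadratic cost in pixels elsewhere); non-local output projection
  zero-initialized so the block starts as the identity.
* **Boxes**: 0-based, half-open pixel coordinates; expansion is total per
  dimension (20% per side at the default 40%), rounded outward so boundary
  pixels are never cropped, then clipped; the per-corner training
  perturbation is a symmetric uniform integer shift in $[-20, 20]$ px,
  degenerate boxes repaired to 2×2. Multi-lesion slices get one box per
  8-connected component; per-box fine masks are unioned.
* **Binarization** of probability maps at 0.5 (the two-channel softmax
  argmax) everywhere downstream.
* **Frozen-model caching**: rejection targets and inputs derive from the
  frozen coarse model and unaugmented slices, so they are computed once per
  training call — bitwise identical to recomputing them each epoch at a
  fraction of the CPU cost.
* **Freeze policy**: the built-in prompt network trains end to end
  (`freeze_policy = "none"`) because it starts from random weights; the
  `"encoder"` policy — encoders frozen, decoder fine-tuned — exists for
  adapters around large pretrained promptable models and is what
  `sam_adapter()` documents as the external default.

## Workflow

```{r}
library(icseg)

spec <- phantom_spec(image_size = 64, lesion_radius_range = c(3, 7), seed = 42)
cohort <- generate_cohort(spec, n_patients = 40, slices_per_patient = 8)

coarse <- build_coarse_net(coarse_net_config(seed = 1))
train_coarse(coarse, cohort, coarse_train_config(epochs = 14, batch_size = 4))
freeze_model(coarse)

reject <- build_rejection_net(
  reject_net_config(in_channels = coarse$feat_channels + 2L, seed = 2))
train_rejection(reject, coarse, cohort, reject_train_config())

fine <- builtin_prompt_net(prompt_seg_config(seed = 3))
train_prompt_seg(fine, cohort, prompt_train_config(epochs = 14))

report <- run_cohort(cohort, coarse, reject, fine, gate_config(0.7))
sweep <- sweep_thresholds(cohort, coarse, reject, fine,
                          t_grid = c(0, 0.2, 0.4, 0.55, 0.7, 0.85))
```

## Known limitations

* The engine is plain dense CPU arithmetic: fine for desk-scale phantoms,
  not for 256×256 clinical volumes at full width.
* The cascade is strictly 2D slice-based; through-plane continuity enters
  only via the 3D lesion-level metrics.
* The simulated manual provider derives boxes from ground truth; a real
  interactive front end is a callback interface
  (`manual_box_provider`), not a UI.
* Only box prompts are supported; clicks, scribbles and mask prompts are
  out of scope.
* NIfTI volumes are assumed co-registered; no bias-field correction or
  registration is performed.
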