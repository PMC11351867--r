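# icseg — interactive cascaded lesion segmentation with automated quality gating

Automatic lesion segmentation of multiparametric MR slices (T2W, ADC,
high-b-value DWI) is good on easy cases and unreliable on hard ones; fully
interactive promptable segmenters are accurate everywhere but need a human
interaction for *every* image. `icseg` implements the intermediate regime:
a **coarse segmentation network** produces an initial mask, a **rejection
network** regresses the Dice quality `s_i` of that mask from the coarse
model's own features and probability map, and a **gate** with threshold `t`
routes only slices with `s_i < t` to (simulated) manual bounding-box
prompts — everything else gets boxes cut automatically from the coarse
mask. A **prompt-conditioned fine network** turns boxes into the final
segmentation:

```
p_c = theta_C(x)                       # coarse probability map
s   = theta_R(cat(f_final, p_c))       # predicted Dice quality
p_f = theta_F(x, bbox(p_c | s))        # fine mask from box prompts
```

All boxes are expanded by 40%; the fraction of slices sent to the user (the
*rejection ratio*) rises with `t`, trading annotation workload against
accuracy. The package ships a seeded multi-channel phantom generator, NIfTI
I/O shared between synthetic and real volumes, CPU training for all three
networks (a compact internal conv-net engine with exact hand-derived
gradients, finite-difference-checked in the test suite), and the complete
evaluation toolbox: Dice, 95th-percentile Hausdorff distance (exact
distance-transform implementation, brute-force-oracle-tested), lesion-level
TPR/PPV/F1 over 26-connected 3D components at overlap threshold 0.1,
quality-regression R², rejection ratios, threshold sweeps, and paired
t-tests.

## Worked example

```r
library(icseg)

spec   <- phantom_spec(image_size = 64, lesion_radius_range = c(3, 7), seed = 1)
cohort <- generate_cohort(spec, n_patients = 40, slices_per_patient = 8)

coarse <- build_coarse_net(coarse_net_config(seed = 2))
train_coarse(coarse, cohort, coarse_train_config(epochs = 14, batch_size = 4, seed = 2))
freeze_model(coarse)

reject <- build_rejection_net(
  reject_net_config(in_channels = coarse$feat_channels + 2L, seed = 3))
train_rejection(reject, coarse, cohort, reject_train_config(seed = 3))

fine <- builtin_prompt_net(prompt_seg_config(seed = 4))
train_prompt_seg(fine, cohort, prompt_train_config(epochs = 14, seed = 4))

sweep <- sweep_thresholds(cohort, coarse, reject, fine,
                          t_grid = c(0, 0.2, 0.4, 0.55, 0.7, 0.85))
sweep$curve
```

This is the computation `scripts/acceptance.R --seed 1` performs; on that
run (about ten minutes on one CPU) it printed:

```
     t rejection_ratio  mean_dsc mean_hd95
1 0.00        0.000000 0.5196367  3.842396
2 0.20        0.375000 0.8134002  1.446772
3 0.40        0.484375 0.8532233  1.070387
4 0.55        0.515625 0.8527657  1.085802
5 0.70        0.562500 0.8648915  1.102223
6 0.85        0.656250 0.8642833  1.102223
```

with a held-out quality-regression R² of 0.70 over the 64 test slices.
Reading the table: at `t = 0` no slice is reviewed, every bounding box is
cut from the coarse mask, and false positives on hard slices drag mean Dice
down to 0.52; as `t` rises, slices whose predicted quality falls below `t`
are routed to simulated manual boxes, the rejection ratio (the reviewer's
workload) grows, and mean Dice of the final segmentation climbs toward the
fully reviewed limit — the quantified workload/accuracy trade-off the gate
exists to expose. The numbers move with the seed (the cohort, all three
trainings and the quality scores are stochastic), but the shape —
monotone rejection ratio, rising Dice, falling 95% HD — is what the method
is about. `run_cohort()` returns the full per-image report (Dice, 95% HD,
decisions, lesion-level detection scores, quality R²) for any single
threshold.

A thin command-line front end (`inst/cli/icseg`) wraps the same functions:
`simulate`, `train`, `run`, `sweep`, `evaluate`.

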