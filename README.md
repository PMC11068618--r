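# pudoseg

Dual-modality 3D segmentation of thin pelvic arteries (the internal
pudendal artery, IPA) from paired CT and T2 MRI for radiotherapy
planning — with CT-only inference as a first-class citizen.

The IPA is a ~4 mm bilateral artery whose radiation dose is linked to
erectile dysfunction after prostate radiotherapy.  It is hard to
segment: on planning CT it is nearly isointense with the muscle it runs
through, the MRI that does show it is only rigidly registered (to
prostate fiducials), historical contours spill into muscle and bone,
and not every patient has an MRI.  `pudoseg` implements a segmentation
model built for exactly these conditions, for medical-image-analysis
researchers and radiotherapy physicists who want a fully inspectable,
CPU-runnable implementation with a synthetic benchmark.

## The model

* **SUNet-MA**: a 3D U-Net limited to two pooling levels with 3D
  squeeze-and-excite blocks, separate CT and MRI encoders, and a
  modality-attention fusion on every skip connection:

      Z_MRI^tran = DefConv(Z_MRI)                 (deformable alignment)
      Z = Z_CT + Z_MRI^tran
      w = softmax( GAP(Z) )                       (per-channel gate)
      Z_enc = w ⊙ Z_CT + w ⊙ Z_MRI^tran

  where `DefConv` is a 3D deformable convolution whose per-voxel,
  per-tap offsets are learned jointly with the kernel (this absorbs
  residual CT–MRI misregistration), and `GAP` is global average
  pooling over space.

* **Modality dropout (MoDO)**: during training the MRI input is
  randomly replaced by zeros per sample, so the trained model degrades
  gracefully — or not at all — when run with CT alone.

* **Noisy-label correction**: the training objective is

      L = L_DSC + w_m · |Pred ∩ CT_muscle| / |Pred|
                + w_b · |Pred ∩ CT_bone|   / |Pred|

  with soft Dice `L_DSC`, `w_m = 0.1`, `w_b = 0.01`, and tissue masks
  obtained by thresholding **raw HU** with the muscle window
  [−29, 150] and the bone window [300, 1200] — a self-supervised
  penalty on predictions that follow sloppy contours into muscle/bone.

Everything is implemented in R (with small Rcpp kernels for the
convolution and deformable-sampling inner loops) on a purpose-built
reverse-mode autodiff tape — every gradient is finite-difference
checked in the test suite.  Evaluation uses spacing-aware DSC (%),
average surface distance and HD95 (mm) backed by an exact anisotropic
distance transform, plus dose-volume parameters (Dmean, V20).

Since no clinical data is distributable, the package ships a seeded
**phantom generator**: bilateral tubular targets in muscle next to
bone, with realistic HU, low CT / high MRI vessel contrast,
controllable CT–MRI misregistration and labels noisily dilated into
muscle and bone.  All tests and experiments run on these phantoms.

## Worked example

```r
library(pudoseg)

# a small seeded benchmark: 8 training + 5 test phantoms
bm    <- make_benchmark(8, 5, spec = phantom_spec(grid = c(24, 24, 16)), seed = 11)
train <- prepare_samples(bm$train, label = "noisy")   # train on noisy labels
test  <- prepare_samples(bm$test,  label = "clean")   # evaluate on ground truth

fit <- sunet(train, variant = "snetma", base_channels = 8,
             epochs = 15, initial_lr = 0.01, modo_probability = 0.5, seed = 1)
print(fit)
#> Squeeze-and-excite U-Net fit (snetma)
#>   base channels 8, 2 pooling levels, modality dropout p = 0.5
#>   loss: soft dice + 0.1 * muscle inclusion + 0.01 * bone inclusion
#>   trained 15 epoch(s); final loss 0.6690

pred <- predict(fit, test[[1]], type = "mask")
evaluate_segmentation(pred, test[[1]]$label)
#> $dsc_percent [1] 21.2   $asd_mm [1] 3.27   $hd95_mm [1] 4.9
#> $n_pred_voxels [1] 1980  $n_gt_voxels [1] 235  $status [1] "ok"
```

The printed numbers mean: after 15 epochs on 8 tiny noisy-labelled
phantoms the model still over-segments (1980 predicted voxels against
a 235-voxel ground-truth tube, DSC ≈ 21 %, mean surface error
≈ 3.3 mm) — far from the clinical
regime (which needs full-size data and training budgets), but enough
for the benchmark's purpose: the same model evaluated **without MRI**
loses nothing when trained with modality dropout (mean test DSC 21.9 %
CT-only versus 21.2 % with both inputs, for this fit), and collapses
without it.  `run_ablation()` reproduces that grid:

```r
ab <- run_ablation(bm, presets = c("mrict", "modo"), seeds = 1:3,
                   epochs = 15, initial_lr = 0.01)
ab$table   # preset x input-mode rows with mean ± sd DSC/ASD/HD95
```

A command-line interface wraps the same pipeline
(`generate`, `train`, `predict`, `evaluate`, `ablate`, `dose-compare`):

```sh
Rscript inst/cli/pudoseg.R generate --out data/ --n-train 8 --n-test 5 --seed 7
Rscript inst/cli/pudoseg.R train    --data data/ --out run/ --preset modo --epochs 15 --seed 1
Rscript inst/cli/pudoseg.R predict  --ct data/test_001/ct.nii.gz --model run/model.ckpt --out pred.nii.gz
Rscript inst/cli/pudoseg.R evaluate --pred pred.nii.gz --gt data/test_001/label.nii.gz --out report.json
```

Every stage writes a JSON run manifest sufficient to re-execute it.

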