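# gmstage

Gray-matter segmentation and disease staging of 2D brain-MRI slices, with
synthetic-phantom validation.

Alzheimer's disease leaves two robust fingerprints on a structural T1 slice:
the cortical gray-matter (GM) ribbon thins and dims, and the CSF-filled
ventricles enlarge, progressing CN → MCI → AD (cognitively normal, mild
cognitive impairment, Alzheimer's disease). `gmstage` implements a
four-phase analysis of these fingerprints for researchers prototyping
segmentation-plus-classification imaging pipelines on a plain CPU:

1. **Whole-brain segmentation** — vanilla U-Net (depth 4, skip connections,
   sigmoid head).
2. **Gray-matter segmentation** — multi-layer U-Net (depth 3, skip
   connections at every level) trained under a class-balanced binary
   cross-entropy

   L = mean( −β·y·log p − (1−β)·(1−y)·log(1−p) ),

   with β = background-pixel fraction by default (a soft Dice loss,
   1 − (2Σpy + s)/(Σp + Σy + s), is the alternative), and the standard
   metric battery: Dice = 2|P∩G|/(|P|+|G|), IoU = |P∩G|/|P∪G|, accuracy,
   precision, recall, F1 (Dice ≡ F1 on binary masks).
3. **Hybrid classification** — a multi-scale convolutional head (parallel
   3×3 / 5×5 / 7×7 branches → LeakyReLU → max pool → adaptive average pool →
   dropout, concatenated to one feature vector) on a pluggable backbone,
   trained by categorical cross-entropy; the standardized feature vectors
   feed one-vs-rest SVMs with decision rule
   f(x) = sign( Σᵢ αᵢyᵢ·exp(−γ‖xᵢ−x‖²) + b ), grid-searched over
   kernel ∈ {rbf, linear} × C ∈ {0.1, 1, 10} × γ ∈ {scale, auto} by
   stratified cross-validated accuracy. Evaluation: per-class
   precision/recall/F1, confusion matrix, one-vs-rest ROC with trapezoidal
   AUC and Youden-optimal thresholds, and the McNemar paired test
   (b−c)²/(b+c) on discordant counts.
4. **Saliency explanation** — |∂(class score)/∂pixel| through the softmax
   head, normalized per map, Gaussian-blurred, Sobel-edge-overlaid, tinted
   red/blue/green for AD/MCI/CN, and quantified as mean saliency over four
   image quadrants per class.

Because the clinical datasets for this task are access-restricted, the
package ships a deterministic **brain-phantom generator**: five concentric
tissue regions (background, skull, CSF, GM annulus, WM core) plus an
elliptical ventricle, with class-dependent GM thickness/intensity and
ventricle size, shape jitter and additive noise — and exact ground-truth
masks. Every stage is exercised end to end on these phantoms.

## Worked example

A scaled-down two-repeat run of the full pipeline (50 phantoms per class at
64×64; about two minutes on one CPU):

```r
library(gmstage)
cfg <- pipeline_config(
  output_root = file.path(tempdir(), "gmstage-demo"),
  n_per_class = 50, image_size = 64,
  seg = list(epochs = 8, base_filters = 16, learning_rate = 1e-3),
  clf = list(epochs = 8, learning_rate = 3e-3,
             branch_channels = 32, backbone_channels = 32, cv_folds = 3),
  run_repeats = 2)
report <- run_pipeline(cfg)
print(report$summary, row.names = FALSE, digits = 3)
```

```
               metric   mean      sd
             val_dice  0.806 0.02097
            test_dice  0.808 0.00916
             accuracy  0.867 0.04714
                f1_AD  1.000 0.00000
                f1_CN  0.789 0.07443
               f1_MCI  0.810 0.06734
               auc_AD  1.000 0.00000
               auc_CN  0.943 0.04596
              auc_MCI  0.893 0.00354
 saliency_gm_bg_ratio 26.075 4.70436
```

Reading the table: `val_dice`/`test_dice` are the GM-segmentation Dice
overlap of the multi-layer U-Net (0.81 at this very small training budget;
the longer study recipe below reaches ≈ 0.98); `accuracy` and the per-class
F1/AUC rows describe the hybrid head + SVM staging of the test split; and
`saliency_gm_bg_ratio` says saliency mass inside the GM annulus is ~26×
denser than over the background, i.e. the classifier's evidence sits on the
tissue whose atrophy defines the disease. Each run directory contains the
config snapshot, a log, per-seed `metrics.csv`, the `summary.csv` above and
the quadrant saliency table `region_saliency.csv`.

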