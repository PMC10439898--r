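# lvquant

Joint segmentation and full quantification of the left ventricle (LV) in
short-axis cine MRI.

Clinical LV assessment rests on eleven per-frame indices — the cavity and
myocardium areas, three cavity dimensions along the IS-AL, I-A and IL-AS
directions, and six regional wall thicknesses (IS, I, IL, AL, A, AS) —
plus the binary cardiac phase (systole/diastole). `lvquant` implements a
task-unified estimator of all of them: a U-Net-like 3D hybrid
CNN–Transformer network segments cavity, myocardium and background in a
5-frame temporal window, while a spatio-temporal convolutional regression
network consumes the raw window together with multi-scale decoder
features of the segmentation path and predicts the indices and phase of
the centre frame. The two paths are trained jointly with the weighted
multi-task objective

```
L = λ3 (λ1 L_CE + λ2 L_Dice) + λ4 (L_MSE + L_BCE),   λ1 = 1, λ2 = 1.5, λ3 = 4, λ4 = 1
```

where `L_Dice` is the class-averaged soft Dice loss
`1 − (2/K) Σ_k (Σ_i y p) / (Σ_i (y + p))`, `L_CE` the pixel-mean
cross-entropy, `L_MSE` the mean squared error over the 11 normalized
indices and `L_BCE` the binary cross-entropy of the phase probability.

The package is self-contained for development and validation without a
clinical dataset:

- a **parametric beating-LV phantom** (`sample_phantom_spec()`,
  `render_subject()`, `generate_dataset()`) with analytically exact
  ground-truth indices derived from the continuous model, not the
  rasterized masks;
- **centroid ray-casting morphometry** (`indices_from_mask()` and
  friends) — the deterministic "Calculation" baseline that measures the
  same indices directly from label masks and doubles as the oracle
  validating both the phantom and the learned regressor;
- the **networks, losses, optimizers** (RAdam for the segmentation path,
  SGD with momentum for the regression path) and subject-level
  **cross-validation** (`train_unified()`, `cross_validate()`,
  `predict_subject()`), running on a compact reverse-mode autodiff engine
  with RcppArmadillo convolution kernels — everything trains and
  evaluates on a single CPU at desk scale;
- **evaluation metrics** (`evaluate()`: per-class Dice and Hausdorff
  distance, per-index MAE and Pearson correlation, phase error rate) with
  `tidy()` / `glance()` / `autoplot()` methods;
- a **command-line interface** (`exec/lvquant`; subcommands `simulate`,
  `indices`, `train`, `crossval`, `segment`, `evaluate`).

Normalisation conventions: areas are divided by the pixel count, lengths
by the image height; physical units are recovered with the pixel spacing
(default 1.5625 mm/pixel), e.g. a normalized dimension error of 0.02 at
80 px is 2.5 mm.

## Worked example

Simulate a small cohort, measure the indices from the masks with the
ray-casting baseline, and compare with the analytic truth:

```r
library(lvquant)

set.seed(1)
subjects <- generate_dataset(5, "realistic")      # in-memory cohort
est <- lapply(subjects, function(s) indices_from_mask(s$masks))
report <- evaluate(lapply(est, function(e) list(masks = NULL, indices = e)),
                   subjects)
report
#> LV quantification report (100 frames, 80px, 1.5625 mm/px)
#>   MAE (norm): area_cav 0.0003  area_myo 0.0005  dim1 0.0054  dim2 0.0045
#>               dim3 0.0048  rwt_is 0.0025  rwt_i 0.0035  rwt_il 0.0023
#>               rwt_al 0.0029  rwt_a 0.0033  rwt_as 0.0023
#>   PCC:        area_cav 1.000  area_myo 0.999  dim1 0.996  dim2 0.997
#>               dim3 0.996  rwt_is 0.995  rwt_i 0.992  rwt_il 0.997
#>               rwt_al 0.994  rwt_a 0.988  rwt_as 0.996
#>   Phase ER:   0.000
```

These are the rasterization floor of an 80 px mask: in physical units
(`report$mae_physical`) about 0.6 mm for the dimensions, 0.3-0.4 mm for
the wall thicknesses and 5-8 mm² for the areas. A
training run on the same kind of data:

```r
model <- build_unified_model(
  seg_config(stem_channels = c(4L, 8L, 16L), hidden = 32L, depth = 1L,
             heads = 4L, decoder_channels = c(12L, 12L, 8L, 6L)),
  reg_config(channels = c(4L, 8L, 32L), recurrence = 1L))
cfg <- train_config(epochs = 50, batch_size = 4, frames_per_subject = 4,
                    seg_lr = 2e-3, reg_lr = 0.15, reg_momentum = 0.95,
                    reg_weight_decay = 0, reg_clip = 2, seg_clip = 5,
                    seed = 1)
history <- train_unified(model, subjects, cfg)
pred <- predict_subject(model, subjects[[1]], cfg)
```

Or from the shell:

```sh
exec/lvquant simulate --subjects 20 --seed 0 --out phantom_data
exec/lvquant indices --data phantom_data --out calc_indices
exec/lvquant crossval --data phantom_data --small --folds 2 --epochs 15 --out cv_out
```

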