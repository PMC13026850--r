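# ffmsnet

Compact morphology-aware semantic segmentation of surgical instruments in
endoscopic images, in pure R (with RcppArmadillo compute kernels).

Endoscopic footage degrades the very cues that identify a thin metallic
instrument — edges and morphology — through blur, glare, smoke, blood
occlusion and unstable illumination, while background pixels vastly
outnumber instrument pixels. `ffmsnet` implements an encoder–decoder
network built to resist that degradation with **≤ 1.5 million trainable
parameters**:

* a **frozen/learnable stem**: alongside a learnable convolution branch, a
  bank of three *fixed* kernels — Sobel-x, Sobel-y and the 4-neighbour
  Laplacian — injects edge magnitude, orientation and curvature maps that
  training can never erode (the kernels are excluded from the optimizer);
* a **tri-atrous bottleneck**: three parallel dilated convolutions (rates
  2/4/6) fuse multi-receptive-field context so morphology survives local
  invisibility;
* a **structure-preserving decoder**: each ×2 upsampling fuses projected
  encoder features through light skip paths (1×1 conv + BN), then
  aggregates a mildly dilated and a standard convolution branch by
  element-wise addition.

Segmentation quality is scored from per-class confusion counts with
IoU `I = tp/(tp+fp+fn)`, Dice `D = 2tp/(2tp+fp+fn)` (so `D = 2I/(1+I)`
exactly), precision, recall, and a tolerance-based boundary F1. Training
uses Adam (lr 5e-4, ×0.1 every 10 epochs, L2 5e-4) with class-weighted
cross-entropy or class-weighted soft Dice losses and five-fold
cross-validation utilities.

Because clinical datasets cannot ship with a package, `ffmsnet` includes a
deterministic **synthetic endoscopic-scene generator** (thin bright
instruments over reddish tissue texture, degraded by blur/glare/occlusion/
smoke/low-contrast with clean pre-degradation masks) so every component is
testable offline, plus **mask-derived scene descriptors** (area ratios,
presence, border touch, variance-of-Laplacian blur score) feeding a
deterministic, non-clinical text prompt for any pluggable summarization
backend.

## Worked example

```r
library(ffmsnet)

model <- build_network(network_config(input_height = 64, input_width = 64), seed = 1)
model
#> seg_model: 64x64x3 -> 2 classes, 66 ops, 1,170,962 trainable parameters (+3 frozen kernels)

spec <- scene_spec(height = 64, width = 64,
                   instrument_width_range = c(5, 12),
                   instrument_length_range = c(30, 80))
pairs <- generate_pairs(spec, 12, seed = 7)

fit <- train_model(model, pairs[1:8], val_pairs = pairs[9:12],
                   cfg = train_config(epochs = 10, batch_size = 4, seed = 7))
evaluate_model(fit$model, pairs[9:12], bf1 = TRUE)
#>   class  dice   iou precision recall   bf1
#> 1     0 0.977 0.956     0.998  0.957    NA
#> 2     1 0.860 0.754     0.762  0.987    NA
#> 3  mean 0.919 0.855     0.880  0.972 0.698
```

After ten epochs on eight synthetic scenes the instrument class (row `1`)
reaches Dice 0.86 on four held-out scenes: the model finds essentially all
instrument pixels (recall 0.99) but still over-segments (precision 0.76);
the boundary-F1 of 0.70 says boundary placement is looser than region
overlap. Longer training closes the gap (the test suite's 200-iteration
run exceeds Dice 0.95 on its training scenes).

Descriptors for a predicted mask, and the prompt they serialize into:

```r
d <- compute_descriptors(pairs[[9]]$image, segment(fit$model, pairs[[9]]$image))
d
#> scene descriptors:
#>   area ratios: 0.823 0.177
#>   border touch: TRUE  blur score: 0.004555533
cat(build_summary_prompt(d, c("background", "instrument")))
```

A command-line interface wrapping the same functions (subcommands
`simulate`, `train`, `crossval`, `evaluate`, `predict`, `describe`,
`params`) is installed at
`system.file("cli", "ffmsnet.R", package = "ffmsnet")`.

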