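# mfafuse

Multi-scale attention fusion and refinement for stacks of co-registered
single-channel images, with segmentation of the fused representation.

Clinical imaging frequently yields several registered views of the same
anatomy — pseudo-modalities differing in contrast, dynamic range and noise.
`mfafuse` implements a **multi-scale feature adaptive fusion network
(MFAFN)**: a shared convolutional encoder decomposes each input
$I_i$ into an $L$-level feature pyramid $F_i^{(l)}$; a per-scale attention
map $A_i^{(l)} = \mathrm{softmax}_{xy}(W F_i^{(l)})$ (softmax over spatial
locations, per channel) aligns features residually,
$\hat F_i^{(l)} = F_i^{(l)} + A_i^{(l)} \odot F_i^{(l)}$; scales are fused
by simplex weights, $F^{(l)} = \sum_i w_i^{(l)} \hat F_i^{(l)}$,
$\sum_i w_i^{(l)} = 1$. A **dynamic feature refinement strategy (DFRS)**
supplies the weights from gradient-L1 saliency,
$w_i^{(l)} \propto \exp(\mathrm{Sal}(\hat F_i^{(l)}))$, and refines each
fused map with gated global context,
$F^{(l)}_\mathrm{ref} = F^{(l)} + \alpha_l\,
\sigma(\mathrm{conv}_{1\times1}[F^{(l)}; \bar F^{(l)}]) \odot \bar F^{(l)}$,
where $\bar F^{(l)}$ is the mean over inputs and $\alpha_l$ is a learnable
scalar initialized to 0. A transposed-convolution decoder with per-scale
skip injection produces a fused image and a segmentation probability map.

Everything runs on one CPU: the network and its reverse-mode gradients are
implemented in R on top of small C++ (Rcpp/RcppArmadillo) kernels — no deep
learning framework required. The package also provides:

* a seeded **phantom generator** (branching vessel-like trees, blob
  polyp-like lesions) rendering registered complementary pseudo-modalities
  with ground-truth masks;
* **degradation simulators** (low light, JPEG-Q30 compression artifacts via
  an 8×8 DCT quantization round trip, 5×5 Gaussian blur, additive noise);
* the classical **Laplacian-pyramid fusion** baseline (max-abs detail rule);
* **fusion metrics** (summed SSIM, histogram entropy, gradient alignment)
  and **segmentation metrics** (Dice, IoU, Precision, Recall);
* a **training harness**: Adam at 1e-4, 5-epoch warm-up + cosine annealing,
  early stopping on validation Dice (patience 10), Dice+CE loss,
  morphological post-processing, plus ablation and robustness benchmarks;
* a CLI: `mfafuse simulate | fuse | train | evaluate | ablate | robustness`
  (launcher script in `inst/cli/`).

## Worked example

```r
library(mfafuse)

# a 32x32 two-pseudo-modality blob phantom with ground truth
cfg <- phantom_config(32, 32, n_modalities = 2, structure = "blob", seed = 7)
ph  <- generate_phantom(cfg)

# classical baseline fusion + quality metrics
fused <- pmin(pmax(laplacian_fuse(ph$images, levels = 3), 0), 1)
unlist(fusion_quality(fused, ph$images))
#>      q_spatial q_spatial_norm         q_info         q_edge
#>      1.2130827      0.6065413      6.4357299     30.8754500

# untrained MFAFN+DFRS forward pass: simplex fusion weights per scale
model <- mfafn_build(2, encoder_config(levels = 4, base_channels = 8), seed = 1)
out <- mfafn_predict(model, ph$images)
round(out$weights, 3)
#>       [,1]  [,2]
#> [1,] 0.501 0.499
#> [2,] 0.510 0.490
#> [3,] 0.516 0.484
#> [4,] 0.507 0.493

# train on a phantom dataset (about 3 minutes on one CPU)
ds <- local({
  c2 <- cfg
  lapply(1:200, function(s) {
    c2$seed <- s
    p <- generate_phantom(c2)
    list(id = s, split = if (s <= 160) "train" else "val",
         images = p$images, mask = p$mask)
  })
})
fit <- train(model, ds, train_config(max_epochs = 30, seed = 1))
round(fit$best_val_dice, 3)
#> [1] 0.865

# segmentation metrics of the trained model on one sample
pred <- (mfafn_predict(fit$model, ph$images)$seg_probs >= 0.5) * 1
seg_metrics(postprocess(pred, min_size = 5), ph$mask)
#> Segmentation metrics:
#>   dice      0.8717
#>   iou       0.7726
#>   precision 0.7726
#>   recall    1.0000
```

The first block prints the summed-SSIM spatial consistency (maximum = N,
here 2), its N-normalized value, the fused image's histogram entropy in
bits, and the gradient-alignment cost (lower is better). The fusion weights
are each scale's softmax-saliency simplex weights over the two modalities —
near-uniform for an untrained encoder. `best_val_dice` is the best
validation Dice reached under early stopping; the final block scores the
post-processed predicted mask against the ground truth.

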