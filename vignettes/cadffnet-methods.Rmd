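---
title: "Dual-view convolutional regression of leaf moisture: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view convolutional regression of leaf moisture: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

During air-curing, a leaf loses water; its lamina colour drifts from green
toward brown, the blade curls inward, and the vein network becomes exposed on
the abaxial (back) surface. The moisture content is the gravimetric fraction

$$\mathrm{MC}\,(\%) = 100 \cdot \frac{M_\mathrm{fresh} - M_\mathrm{dry}}{M_\mathrm{fresh}},$$

and the task is to regress it from a *pair* of RGB photographs — front
(adaxial) and back (abaxial) — because neither view alone carries all the
information once the blade curls.

`cadffnet` implements a dual-branch convolutional regression network:

* **Two independent residual backbones** (depths 18/34/50/101, standard
  basic/bottleneck block plans) process the front and back images in
  parallel. No parameters are shared between branches.
* **Shared channel attention (DECA)** after stages 2–4: the two branches'
  same-stage feature maps are summed, globally average-pooled to a length-C
  descriptor, convolved along the channel axis with a short adaptive 1-D
  kernel (zero padding, no bias), passed through a sigmoid, and the resulting
  per-channel weights multiply *both* branches. The kernel size is
  $K = \lfloor (\log_2 C + b)/\gamma \rfloor$ rounded up to odd, with
  $\gamma = 2$, $b = 1$ (so $C = 64 \mapsto 3$, $C \in \{128,256,512\}
  \mapsto 5$). The reweighted maps replace the features fed to the next
  stage, which is what makes the branches interact.
* **Multi-scale fusion (MSCFF)** after stage 5: the two maps are
  concatenated ($2C$ channels), probed by parallel $3{\times}3$ and
  $5{\times}5$ conv + BN + LeakyReLU branches ($2C \to 2C$ each), and the two
  scale branches compete per channel: the pooled $4C$ descriptor passes
  through a two-layer squeeze bottleneck (reduction ratio $r = 16$), a
  softmax converts the logits into branch weights $S_1, S_2$, and the output
  is the residual combination $O = Y + S_1 \odot Y_1 + S_2 \odot Y_2$.
* **Regression head**: global average pooling and one affine map to a single
  scalar. No output nonlinearity; predictions are unconstrained reals and
  clipping to $[0, 100]$ is never applied during optimisation or metrics.

Training minimises the mean squared error on rescaled labels
(`target_scale = 0.01`, i.e. percent mapped to $[0,1]$) with Adam
(learning rate $10^{-4}$, batch size 16); metrics
($R^2$, RMSE, MAE) are always computed after rescaling predictions back to
percent, so `target_scale` cannot affect reported values for a fixed set of
weights.

All tensor math is native: convolutions are im2col + one BLAS GEMM, and the
backward passes are hand-derived and covered by finite-difference tests. No
deep-learning framework is required, which is also why the package defaults
to slim profiles (`base_width = 16`, 64 px inputs) for anything that trains
during tests.

## Numerical and design choices

Several details are underdetermined by the method description; the package
fixes them as follows and exposes flags where the alternative is defensible.

* **Kernel-size rule grouping.** The printed rule is typographically
  ambiguous between $(\log_2 C + b)/\gamma$ and $\log_2 C + b/\gamma$. The
  first reading — the established efficient-channel-attention convention,
  truncation then increment-to-odd — is implemented
  (`adaptive_kernel_size()`), and the choice is fixed rather than
  configurable because the second reading would change every kernel size
  silently.
* **Attention convolution.** Zero padding $(K-1)/2$, no bias — again the
  established convention; neither is stated in the method description.
* **Squeeze dimensions.** The two dense layers are $w_1 \in
  \mathbb{R}^{(4C/r)\times 4C}$ and $w_2 \in \mathbb{R}^{4C\times(4C/r)}$.
  A description that gives both layers the same shape cannot produce a
  length-$4C$ logit vector, so the second layer maps the bottleneck back up;
  both layers carry biases initialised to zero, so an untrained module
  weighs the two scale branches exactly evenly.
* **Softmax scope.** The softmax is applied *pairwise*: for every channel
  $c \le 2C$, the pair $(S'_c, S'_{c+2C})$ is normalised, so
  $S_1[c]+S_2[c]=1$ exactly and the fused magnitude is scale-stable. This is
  the selective-kernel convention and the reading under which the weights
  "coordinate the two scale branches at the channel level". The literal
  full-vector softmax is available via `softmax_scope = "full"`.
* **Activations and normalisation.** LeakyReLU slope 0.01 (unstated);
  batch norm with biased batch variance, momentum 0.1, $\varepsilon =
  10^{-5}$; evaluation always uses running statistics.
* **Initialisation.** He-normal for convolutions, uniform
  $\pm 1/\sqrt{\text{fan-in}}$ for dense layers, drawn from a stream seeded
  by `model_config(seed=)`. ImageNet pretraining is not used anywhere: it is
  never stated in the protocol and tests must not require downloads.
* **Resizing.** Bilinear, half-pixel-centre convention; the interpolation
  kernel is unstated in the protocol and bilinear is the common default.
* **Folds.** Seeded uniform shuffle then contiguous slicing; sizes differ by
  at most one. The split is unstratified — whether the original split was
  stratified by curing day or leaf is unknown, and "randomly divided" is the
  plain reading.
* **Training schedule.** Epoch count, LR schedule and early stopping are
  unstated; the harness trains a fixed number of epochs and keeps the
  checkpoint with the best validation MAE. Cross-validation standard
  deviations use the $n-1$ sample convention.
* **Head.** No dropout (unstated); single-branch baselines use the identical
  head geometry on $C$ channels so dual-vs-single comparisons isolate the
  second view.
* **Config files.** JSON rather than YAML (no YAML parser in the supported
  dependency set); field names mirror `model_config()`/`train_config()`.
* **Checkpoints.** RDS files pairing the configuration with all parameters
  (including batch-norm running statistics), so evaluation is
  self-describing.

## The synthetic generator: what it emulates, and what it does not

No public dataset of paired curing images exists, so the canonical test
input is synthetic (`render_pair()`, `generate_dataset()`,
`synth_dataset()`). Each sample is an elliptical "leaf" on a white
background (matching the white background board of the imaging rig), and the
three phenomena that make dual-view imaging informative are mapped linearly
onto a latent moisture value in $[0,1]$:

* lamina colour interpolates from a dry brown (0.45, 0.33, 0.12) to a wet
  green (0.20, 0.55, 0.15) — so the *front green-channel mean increases*
  with moisture;
* the lamina's horizontal semi-axis shrinks to `curl_min_width_frac`
  (default 0.45) as the latent falls — inward curl;
* the back view is lightened by `back_lightening` (default 0.25) and carries
  a midrib plus `vein_count` (default 6) lateral veins whose darkening
  relative to the lamina scales with $(1-\text{latent})\cdot
  \texttt{vein\_contrast\_max}$ — so the *vein/lamina contrast decreases*
  with moisture, vanishing exactly at latent 1.

Gaussian pixel noise (`noise_sd`, default 0.02) and an optional per-view
brightness jitter are added last; every byte of output is a pure function of
the arguments and the seed. Default `illumination_jitter` is 0 so noise-free
renders hit the colour endpoints exactly.

Two modes control the information structure:

* **joint** — one latent drives both views; the label is $100\times$ the
  latent. This is the ordinary regression benchmark.
* **split** — two latents, drawn i.i.d. $U(0,1)$, and the label is their
  mean $\times 100$. Each view's *entire* appearance (colour, curl, vein
  contrast) is governed only by its own latent. This is deliberate: if the
  curl geometry were shared between views, the back image would leak the
  front latent and the information cap would dissolve. As built, a predictor
  seeing one view can explain at most half of the label variance
  ($R^2 \le 0.5$ up to noise), while a dual-view model can approach 1 —
  a synthetic analogue of the dual-vs-single ablation gap. Because the label
  is derived from the latents, `label_range` applies only to joint mode.

What a green test on this generator does **not** establish: robustness to
real lamina texture, specular highlights, occlusion between overlapping
leaves, camera pose or illumination fields, or any biological covariate
(variety, curing day). The generator's job is statistical structure, not
botany, and conclusions about field performance require field data.

## Test-time scales

The heavy acceptance properties train the slim profile (depth 18,
`base_width = 16`, 64 px) on 400 training / 100 validation pairs. To fit a
single-CPU time budget, the parameter-recovery property runs 15 epochs and
the dual-view-advantage property 8 epochs per model, instead of the ~30 a
full run would use; the pass thresholds ($R^2 \ge 0.8$; single-view
$R^2 \le 0.65$ and a dual margin of $\ge 0.1$) are unchanged. A longer run
of the same configuration is reproducible via:

```{r}
library(cadffnet)
params <- leaf_render_params(side_px = 64L, mode = "joint")
train <- synth_dataset(400, params, seed = 101)
val <- synth_dataset(100, params, seed = 202)
fit <- train_model(model_config(depth = 18, base_width = 16, seed = 11),
                   train, val, train_config(epochs = 30, seed = 12),
                   verbose = TRUE)
evaluate_model(fit$model, val)
```

## Known limitations

* Double-precision CPU training only; wall-clock cost scales roughly with
  `base_width`² and image area, so the full-width 224 px model is usable for
  inference-shape checks but impractical to train here.
* The two printed variance figures for the same cross-validated model in the
  source material differ slightly between sections; the harness makes no
  attempt to reconcile them and always reports its own fold statistics.
* Whether independent-test evaluation should use a fold ensemble is
  unspecified; `run_ablation()` retrains a single final model on the full
  training set, which is the simplest defensible default.
* JPEG decoding is supported for input images, but the generator always
  writes PNG (lossless, deterministic byte-for-byte).
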