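---
title: "Reconstructing perceived faces from ROI responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing perceived faces from ROI responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facerecon)
```

# The problem and the model

Face-selective regions of visual cortex carry attribute-specific
information about a face a person is looking at: expression in the dorsal
pathway (pSTS, amygdala), identity in the ventral pathway (FFA, aIT),
holistic information in OFA and low-level structure in V1. `facerecon`
implements a three-stage decoder that turns per-stimulus voxel responses
from such regions of interest (ROIs) into a rendered face image:

1. **Multi-task attribute network.** A convolutional network with a
   shared trunk and three branches classifies a face image's expression
   (7 classes), identity (N classes) and gender (2 classes)
   simultaneously, trained with the weighted joint loss
   $\mathrm{Loss} = \alpha_1\,\mathrm{loss}_1 + \alpha_2\,\mathrm{loss}_2
   + \alpha_3\,\mathrm{loss}_3$, $\alpha_1+\alpha_2+\alpha_3 = 1$
   (default $(0.4, 0.3, 0.3)$). The architecture family is indexed by a
   *split point* $s \in \{0,\dots,7\}$: how many of the seven units (five
   conv blocks, two FC layers) are shared before branching. The
   multi-dimensional face code is
   $z = (t_{id}, t_{exp}, t_{gen})$ — the penultimate identity-branch
   activations plus the two softmax heads — of dimension
   `fc_width + 7 + 2` (521 at full scale).
2. **Linear brain-to-feature regression.** Per attribute, ordinary least
   squares without intercept from an ROI group's voxel responses $S$ to
   the feature block $T$: $W = (S^\top S)^{-1} S^\top T$, prediction
   $\hat T = S_{new} W$. The proposed ROI grouping decodes expression
   from {V1, OFA, amygdala, pSTS} and identity/gender from
   {V1, OFA, FFA, aIT}; alternative strategies (V1 only, all six ROIs,
   and constraint ablations) are provided.
3. **Multi-conditional GAN.** A DCGAN-style generator maps $z$ through a
   fully-connected layer onto a $4\times4$ grid and transposed
   convolutions up to the image; the discriminator adds three attribute
   heads next to its realness head. The discriminator maximises the
   adversarial term minus $\lambda_D$ times six binary-cross-entropy
   terms (each attribute head on real and generated images, targets
   $t_{id}, t_{exp}, t_{gen}$); the generator minimises its adversarial
   term plus $\lambda_G$ times the mean absolute error against the
   paired real image. Defaults $\lambda_D = \lambda_G = 20$, batch 16,
   one-sided label smoothing with real target 0.9.

Cross-subject decoding projects each subject's responses onto a
per-subject PCA eigen-space (default 56 components), maps the test
subject's coordinates into the training subject's space by a
least-squares linear transform estimated from shared stimuli, and pushes
them through the training subject's regression and generator.

# Synthetic study conditions

Real stimulus photographs and fMRI recordings are not redistributable, so
the package ships a generator with a known ground truth; every
quantitative claim in the test suite is made against these conditions.

**Stimuli.** Grayscale glyph faces with an exact factorial structure:
identity draws six continuous shape parameters (outline radii, eye
spacing/height/size, nose length) from a seeded Normal; expression sets
mouth curvature and eyebrow slope to one of 7 equally spaced levels;
gender (identity parity by default) switches jaw width and a dark hair
band. The full-scale layout mirrors a 952-image set of 136 identities
under 7 expressions; desk-scale tests use 8–26 identities. Default
image size is 64×64 (a power of two for the transposed-conv generator;
330×450 photographs are not), and tests use 16–32 px. At 16 px adjacent
mouth-curvature levels can rasterise identically; all factorial cells are
pairwise distinct from 32 px upward (asserted in the suite), so
image-similarity statistics are computed at ≥32 px.

**ROI responses.** `response(run, stim, roi) = z(stim) W_{true}(roi) +
ε`, ε i.i.d. Normal(0, `noise_sd`²) per run, stimulus and voxel (real
GLM beta noise structure is unspecified, so independence is the neutral
choice). Six ROIs × 56 voxels (a 6-mm sphere's worth) × 5 runs, of which
3 train and 2 test, matching the seen-image protocol; unseen-image runs
use stimulus-level cross-validation (126/14 at full scale). Selectivity
is realised by zero weight rows: pSTS/amygdala encode only the expression
block, FFA/aIT only identity+gender, V1/OFA everything. Nonzero weights
have SD `1/sqrt(active dims)` so each voxel's signal variance is about 1;
the default `noise_sd = 1` therefore means unit-SNR voxels — strong
enough for near-ceiling seen-image decoding at 140 stimuli, weak enough
that single-ROI decoding is not trivially perfect.

**Encoding features.** The simulator's ground-truth features are
label-derived: a fixed Gaussian embedding per identity (default 16-d),
one-hot expression and gender. They stand in for trained-network features
wherever the downstream stages are exercised in isolation
(`feature_source = "mtdln"` switches the pipelines to features extracted
from a trained multi-task network).

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alphas` | (0.4, 0.3, 0.3) | task weights of the joint loss |
| `split_index` | 4 | shared units before branching |
| `learning_rate`, `batch_size`, `epochs` | 0.001, 32, 500 | SGD budget of the classifier (desk runs use tens of epochs and a larger rate) |
| `l2_rate`, `dropout` | 0.001, 0.5 | regularisation of the first / second branch FC layers |
| `lambda_D`, `lambda_G` | 20, 20 | attribute-BCE and MAE weights of the GAN |
| `label_smooth` | 0.9 | real-label target of one-sided smoothing |
| `voxels_per_roi`, `n_runs` | 56, 5 | simulated ROI geometry |
| `noise_sd` | 1 | run-noise SD, ≈ 1/SNR per voxel |
| `k` (eigen-space) | 56 | PCA components per subject; treated as a free parameter (it coincides with the per-ROI voxel count) |
| `n_repeats` | 40 | resampling repeats of the accuracy statistics |

# Evaluation statistics

Per-image metrics are computed on the 0–255 scale: MSE; PSNR
$= 10\log_{10}(255^2/\mathrm{MSE})$ (infinite for identical images, with
a warning); and SSIM from *global* image statistics — one window spanning
the whole image, exactly as the formula
$(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)\,/\,((\mu_x^2 + \mu_y^2 +
C_1)(\sigma_x^2 + \sigma_y^2 + C_2))$ reads, with the standard constants
$C_1 = (0.01\cdot255)^2$, $C_2 = (0.03\cdot255)^2$. A mean-of-sliding-
windows variant is available (`ssim_windowed()`) but is not the default.

**SSIM accuracy** scores each reconstruction 1 when its SSIM to the
ground truth exceeds its SSIM to a distractor drawn uniformly from the
pool excluding the ground truth; the per-repeat accuracy is the mean over
test images, 40 repeats draw fresh distractors, and a one-sample t-test
against 0.5 (Benjamini–Hochberg across conditions; the FDR method is a
choice, as only "FDR" is conventionally specified) summarises the
distribution. SSIM ties count as failure; they are measure-zero for
distinct continuous-valued images.

**Reconstruction accuracy** is the feature-space analogue used for
per-ROI contribution maps: predicted attribute features are compared by
Euclidean distance to the image's own true features versus a random
distractor image's true features (reported in %, chance 50). Here one
numerical choice departs from a literal uniform draw: distractors are
drawn among images whose *true feature vectors differ* from the test
image's. With categorical blocks (one-hot gender, per-identity
embeddings) many images share one true vector; such images are no foil at
all, and counting their inevitable exact ties as failures drives an
uninformative predictor to ≈25% rather than 50% on the gender block.
Excluding identical-feature foils is the feature-space analogue of
excluding the ground-truth image itself from the SSIM pool and restores
the 50% chance level the statistic is tested against.

Two further caveats are worth knowing when reading the statistics:

* With a *fixed* test set the 40 repeats only resample distractors. Each
  image's chance-level win probability is its truth's similarity rank
  among the pool — uniform on $[0,1]$ under independence — so the
  repeat-mean concentrates on an image-conditional value that deviates
  from 0.5 with SD $\approx 0.29/\sqrt{n}$, while the repeat-to-repeat
  SE is several times smaller. A t-test over repeats is therefore
  anticonservative under the null. The suite's null-calibration checks
  aggregate accuracies across independent stimulus draws so the test
  sees the image-sampling variance too; single-draw runs should read the
  t-test as "distractor-resampling precision", not as a calibrated null
  test.
* The gender block has two one-hot classes, so after duplicate-foil
  exclusion every distractor is *the* opposite-gender vector and the
  per-image outcome is deterministic: the 40 repeats are identical and
  the t statistic degenerates to 0 or ±∞. Gender results should be read
  by their mean.

The open-set identity evaluator follows the distance-threshold protocol:
same/different-identity image pairs (900 + 900 at full scale), Euclidean
distances between penultimate identity-branch features, 10 groups, each
scored with the accuracy-maximising threshold of the other nine
(smallest such threshold on ties).

# Numerical and design choices

* **Network engine.** Both networks run on a compact pure-R conv-net
  engine (im2col gather indices; the adjoint scatter as a sparse matrix
  product; transposed convolution as the exact adjoint of a strided
  convolution). Every layer's backward pass is verified against central
  finite differences in the test suite.
* **Feature definition.** "Last two layers" is realised as the 512-d
  (desk: `fc_width`-d) penultimate identity FC plus the 7-d and 2-d
  softmax heads, because 512+7+2 matches the stated 521-d code and
  softmax outputs are already valid BCE targets. Identity features are
  taken after the ReLU, before dropout (evaluation mode).
* **GAN targets and gradients.** The attribute BCE targets are the
  continuous feature vectors as the loss is written (the identity block
  sigmoid-squashed into [0,1]); a one-hot alternative is behind
  `onehot_targets`. The generator trains with the non-saturating
  $-\log D(G(z))$ gradient by default (the DCGAN convention; the
  saturating form is available via `nonsaturating = FALSE`), while
  `generator_loss()` always reports the printed saturating objective.
  The discriminator id-head width equals the id block length of the
  conditioning features. Optimiser: Adam, lr 2e-4, β₁ 0.5 (unspecified
  upstream; DCGAN convention). Label smoothing touches only the real
  adversarial target.
* **Regression.** No intercept, matching the normal-equations formula
  literally; optional mean-centering behind a flag. Training runs enter
  as stacked independent rows, prediction runs are averaged (more
  training samples, less test noise; both modes exposed). Singular
  $S^\top S$ falls back to the minimum-norm SVD solution with a warning.
  All feature dimensions are solved jointly — identical to per-column
  regressions.
* **Constraint ablations.** Dropping an attribute constraint zeroes that
  block of $z$ before conditioning the generator.
* **Cross-subject transform.** Unconstrained least squares on
  eigen-coordinates by default (orthogonal Procrustes behind a flag);
  the inter-subject regressions read eigen-coordinates rather than
  back-projected voxels (smaller, better-conditioned design; the voxel
  route is exposed). With test subject ≡ training subject the chained
  route reproduces the intra-subject predictions to numerical precision
  (~1e-13; the fitted transform is the identity only up to floating
  point), and the rendered 8-bit images agree bit for bit.
* **Seeding.** Every experiment takes one integer seed fanned out to
  stages through a fixed integer map (`child_seed`), so any stage can be
  rerun in isolation and full manifests are reproducible run-to-run.

# Problem sizes used by the suite

Architecture, loss and metric identities are checked on toy tensors.
Training-dependent properties use: a 12-identity, 16-px classifier run
(15 epochs, SGD rate 0.02) for the history/gender checks; a 56-image,
32-px GAN (40 epochs, Adam 1e-3, widths 16/(8,8,16,16)) for the
ablation ordering across 3 seeds and the conditioning checks; 140
validation stimuli (20 identities × 7 expressions), 6 ROIs × 56 voxels ×
5 runs at unit noise for selectivity recovery; and 10 independent
140-image draws for the null calibrations. These sizes are the package's
reference desk-scale conditions; absolute accuracies from GPU-scale
training on photographic data are out of scope throughout.

# What passing tests do and do not show

The synthetic generator makes ground truth exactly linear in known
features with i.i.d. Gaussian run noise and perfectly factorial labels.
Passing selectivity recovery and null calibration therefore shows the
*machinery* is correct — it does not show that real BOLD responses are
linear in CNN features, that real noise is i.i.d., or that photographic
face attributes are as separable as glyph parameters. Glyph faces have no
texture, pose or lighting variation, so reconstruction quality numbers
are not comparable to those obtainable on photographs; only directions
(e.g. the full conditional model outperforming the plain conditional GAN
on pixel MSE) and calibrations transfer as claims.
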