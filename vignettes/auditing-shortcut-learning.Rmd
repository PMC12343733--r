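---
title: "Auditing and unlearning shortcut behaviour in small CNNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and unlearning shortcut behaviour in small CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classifiers trained on observational data routinely pick up *spurious
correlations*: features that predict the label in the training set but are
causally unrelated to the task — a microscope's dark rim around a lesion, a
timestamp burned into an endoscopy frame, a scanner's brightness signature, a
noisy electrode in one ECG lead. A model exploiting such a shortcut looks
excellent on a held-out split drawn from the same biased distribution and
fails as soon as the artifact decouples from the label.

`biaslens` implements a complete audit-and-revise loop for this failure mode
on desk-scale convolutional models:

1. **Reveal** — surface suspicious prediction behaviour by clustering
   relevance patterns (data perspective) and by outlier analysis of concept
   representations (model perspective).
2. **Model the bias** — represent the artifact as a direction in a layer's
   channel space (a concept activation vector, CAV).
3. **Annotate** — rank samples by their projection onto the bias direction,
   refine labels with a human (or oracle) in the loop, and localize the
   artifact in input space.
4. **Revise** — unlearn the shortcut by gradient-penalty finetuning or by
   training-free projection editing.
5. **Re-evaluate** — quantify shortcut reliance before and after with a fixed
   metric suite.

Everything is exercised end-to-end on synthetic bundles with *controlled*
artifacts and ground-truth masks, so each mechanism is testable against known
truth.

## Synthetic study conditions

`generate_image_dataset()` draws grayscale images whose class signal is a
foreground *shape* of matched area (disc, ellipse, square, striped bar) over
Gaussian texture noise; mean intensity is uninformative by construction, so a
model must read geometry. `generate_signal_dataset()` draws periodic
multichannel signals whose classes differ in beat amplitude and width. Both
reach > 95% clean validation accuracy with the bundled three-block CNN in
tens of seconds on one CPU — deliberately easy enough that mitigation effects
are measurable above noise, and hard enough that the artifact is the cheaper
feature to learn.

Four controlled artifacts are available, mirroring the common clinical
imaging artifact families:

* `ring` — a thick black circle (microscope-like rim); ground-truth mask is
  the annulus.
* `corner_patch` — a bright striped box near a corner (timestamp-like), with
  per-sample placement jitter so that no single pixel is a shortcut.
* `brightness` — a global additive shift, clipped to `[0, 1]`; flagged
  *non-localizable*, so localization metrics are skipped for it.
* `static_noise` — a high-amplitude noise burst on one channel of a 1D
  signal over a configured segment.

An `artifact_spec(kind, insertion_rate_p = p, target_class = k)` is inserted
into exactly `round(p * n)` training samples of class `k` — the
spurious-correlation strength is constructed, not sampled. The biased test
split carries the artifact in *every* sample of *every* class, so shortcut
reliance shows up as a clean-vs-biased accuracy gap. The preset insertion
rate is `p = 0.8`: strong enough that the artifact dominates the attacked
class, while the remaining 20% clean samples keep the true class signal
learnable — which is what keeps a vanilla model's *clean* accuracy high, the
regime in which before/after mitigation comparisons are meaningful. At
`p = 1` with two classes, a from-scratch model has no incentive to learn the
attacked class's true signal at all and clean accuracy collapses to chance;
we therefore run the mitigation study at the preset `p = 0.8`.

What the generator does **not** emulate: photorealistic texture, anatomical
variability, label noise, correlated artifact–pathology co-occurrence, and
concept entanglement between the artifact and valid features. Passing tests
on these bundles demonstrate that the *mechanisms* work; they do not certify
performance on clinical data.

## Models

`build_model()` constructs a three-block CNN (conv 3×3 → ReLU → max-pool 2×2,
widths 8/16/32) followed by flatten and a single linear head; the 1D variant
uses length-9 kernels and pools along time. Every layer is named; the model
can be split at any layer `l` into a feature extractor `a_l` and a head, the
basis for all concept-level operations. A deliberately *linear* head keeps
latent-gradient penalties at the last pooled layer close to global
constraints on the head weights (see Mitigation below). Training is Adam on
softmax cross-entropy, fully seeded; `train_model()` records per-epoch loss,
penalty and clean-validation accuracy.

## Attribution

The LRP engine uses a composite rule set standard for small CNNs:

* dense layers — ε-rule (ε = 1e-6);
* convolutions — z⁺ rule (positive weights only), which is stable on the
  non-negative activations that follow ReLUs;
* the *first* convolution falls back to the ε-rule when the input itself can
  be negative (real-valued signals), since z⁺ assumes non-negative inputs;
* max-pooling — winner-take-all routing to the recorded argmax;
* ReLU — identity.

With zero bias terms every rule redistributes relevance exactly, so the
input heatmap sums to the initialised output relevance (conservation to
< 1e-3 relative on random bias-free networks — one of the package's
acceptance properties); trained bias terms absorb a small share. 2D heatmaps
are summed over input channels for display and clustering.

Concept-conditioned attribution initialises the latent relevance at the
CAV's layer as `a_l(x) ∘ h` and propagates it down with the same rules. Two
initialisation modes exist: `"dense"` (all spatial positions — the default
for localization) and `"max"` (winner-take-all per channel), which places the
initialisation at each channel's spatial argmax so that its total equals the
max-pooled bias score `hᵀ maxpool(a_l(x))` exactly — the pooling-consistent
case in which score and attribution agree by construction.

## Concept vectors

`fit_cav()` offers the two supervised estimators: the weight vector of a
soft-margin linear SVM (cost 1, unscaled — the classical CAV, and the better
ranking tool), and the *pattern* estimator — the difference of
class-conditional means — which recovers the concept's signal direction and
is robust to correlated distractor directions that tilt discriminants. CAVs
are stored unnormalised with their norm recorded; consumers normalise
explicitly where the mathematics requires a unit vector. Default spatial
pooling is the per-channel spatial maximum. Single neurons are one-hot CAVs;
unsupervised candidates come from PCA or a hand-written multiplicative-update
NMF (no NMF package is part of the package's dependency set).

In controlled settings the package fits artifact CAVs by *paired insertion*
(`paired_artifact_cav()`): the artifact is copy-pasted onto clean reference
samples and the CAV is fitted on the pairs. Pairing removes class information
from the contrast — important because at high insertion rates artifact
presence and class are nearly confounded, and a CAV fitted on raw
artifact-vs-clean labels would partly encode the class itself.

## Reveal

The data perspective clusters relevance rows — flattened input heatmaps or
spatially max-pooled latent relevances — by spectral clustering on a Gaussian
affinity over cosine distances. Parameters the method reference leaves open
were fixed as: median-heuristic kernel bandwidth, candidate cluster counts
2–5, k-means on the row-normalised Laplacian eigenvectors, and ranking of
candidate clusterings by a ridge-regularised two-class Fisher criterion
(each cluster against the rest, computed in the spectral embedding).
Running without a class filter is allowed but warned, since clusters then
tend to reproduce classes rather than prediction strategies.

The model perspective computes channel-wise cosine distances of pooled
latent relevance columns and embeds the m×m distance matrix in 2D. The
dimension-reduction backends are classical multidimensional scaling and PCA
(the environment provides no UMAP/t-SNE implementation; for m ≤ a few dozen
channels a metric embedding of the distance matrix serves the same
inspection purpose). Outliers are scored with a from-definition Local
Outlier Factor (k-distance, reachability, local reachability density;
default k = min(10, n−1)). The real-sample representation analysis assigns
each neuron its top-q activating reference samples and represents it by the
mean activation of all neurons on those samples. Prototype summaries fit a
Gaussian mixture (via `mclust`) to pooled latent relevance rows; constrained
covariance models act as the regularisation fallback when a component
covariance is near-singular.

## Annotation

`rank_samples()` scores a dataset against a CAV with activation or
class-conditional relevance projections; AUROC uses the exact rank-sum
formula and AP the standard precision-at-positives mean.
`iterative_refinement()` abstracts the human annotator as an injected oracle
callback: each round fits a CAV on current labels, queries the oracle for the
top-ranked unconfirmed samples, and never relabels an oracle-confirmed
entry. Budget and rounds are configuration parameters (no stopping rule is
prescribed).

`localize_bias()` builds the soft mask from the positive part of the
concept-conditioned heatmap (evidence *for* the concept), clips it at its
99th percentile so single extreme pixels cannot dominate the histogram, and
binarises by Otsu's threshold (256-bin between-class-variance maximiser,
written in the package and cross-checked against an independent
implementation in the tests) or a top-quantile rule.

A caveat the ring artifact demonstrates: relevance rules of the `x ⊙ (·)`
family assign zero relevance to zero-valued (black) pixels, and models key on
the *contrast border* of a dark rim rather than its area. Localization of
the ring therefore concentrates in a one-pixel band around the annulus and
its IoU against the filled disc stays low — the correct reading is that the
model's concept of the artifact is the border, not that localization failed.

## Mitigation

Two finetuning penalties and two training-free edits:

* **Input-gradient penalty (RRR)** — `Σ (mask ⊙ ∂ log p(y|x)/∂x)²`, requiring
  ground-truth masks; the gradient is taken on the true-class log-probability
  for bounded scale. Not applicable to the non-localizable brightness
  artifact.
* **Latent concept-gradient penalty (RR-ClArC)** —
  `Σ_pos (hᵀ ∂f_y/∂a_l[pos])²`: the squared directional derivative of the
  true-class score along the CAV, per spatial position. The per-position form
  is a strictly stronger constraint than penalising the spatially summed
  derivative and is what the package optimises. The CAV is frozen during
  finetuning.
* **Projection edit (P-ClArC)** — inserts `a' = a − ĥ(ĥᵀa − z0)` after the
  concept layer, per spatial position. The default `z0` is the mean
  projection value of labelled clean training samples; `0` is the
  alternative. Applied per spatial position (a pooled projection would not
  leave the layer's shape invariant).
* **Reactive edit (rP-ClArC)** — the same projection gated per sample on the
  pooled bias score; the default threshold is the 95th percentile of clean
  training samples' scores. Below-threshold samples pass through
  bit-identically.

Both penalties need gradients *of* gradients. The networks here are
piecewise linear, so the package implements exact double-backpropagation
with frozen ReLU/pooling gates: the penalty's parameter gradient is
assembled from a Jacobian-vector (forward) pass of the perturbation
direction and the cached backward deltas, layer by layer — the same
outer-product structure as ordinary weight gradients with activations
replaced by the propagated perturbation. For RRR the softmax probabilities
are treated as constants when differentiating the penalty (the standard
estimator; it avoids third-order terms).

Editing is *declarative*: one projection slot exists per layer and
re-applying an edit with the same concept replaces the descriptor. This is
what makes double application exactly — bitwise — equal to single
application; numerically re-projecting would differ in the last ulp.

Two observations from the controlled experiments shaped the defaults of
`mitigation_study()`:

* A single linear direction can only neutralise an artifact that the model
  encodes compactly. The brightness shift is near rank-one in every layer by
  construction and is faithfully removed; a high-contrast patch learned from
  scratch by a small CNN spreads over many channel-position combinations,
  and both penalty and projection leave residual shortcut routes. The
  default mitigation study therefore uses the brightness artifact — the
  regime the concept-based methods are designed for (and the regime that
  pretrained backbones put real artifacts into).
* Gradient penalties act at the training points; with a trainable nonlinear
  stage between the penalised layer and the head, cross-entropy re-routes
  the artifact around the frozen direction. Penalising at the last pooled
  layer, where the head is linear, turns the penalty into a near-global
  constraint on head weights and is the effective configuration.

## Evaluation

`evaluation_report()` aggregates: clean/biased test accuracy; mean artifact
relevance (share of *positive* input relevance inside the ground-truth mask —
sign convention recorded, negative evidence excluded); localization IoU and
relevance of the concept-conditioned masks; retrieval AUROC/AP; and TCAV —
the fraction of samples whose target-class score has a positive directional
derivative along the unit CAV at the concept layer, reported as
ΔTCAV = |TCAV − 0.5|. Exact zero derivatives count 0.5 each, so a
projection-edited model (whose derivative along ĥ is identically zero) sits
at TCAV = 0.5, ΔTCAV = 0 — the "no sensitivity" reading. TCAV is reported on
both the clean and the biased test split, since the method reference leaves
the choice open. IoU of two empty masks is 1 (flagged); artifact relevance
of an empty heatmap is 0 (flagged) and of an empty mask undefined (`NA`,
flagged).

Two TCAV subtleties worth knowing: below a purely linear head the
directional derivative is the same for every sample, so TCAV is degenerate
at {0, ½, 1} there — measure it at a layer with nonlinearities above (the
default study uses the second pooling layer); and the P-ClArC pooled-score
invariant `score ≡ z0·‖h‖` holds exactly under *mean* spatial pooling (any
linear pooling commutes with the per-position projection) but not under max
pooling, so the invariant is checked with mean pooling.

## Problem sizes and reproducibility

The bundled studies run on one CPU: 32×32 images, 40–100 training samples
per class, 10–20 epochs (seconds to ~1 minute per model), three seeds for
the before/after mitigation comparison, signals of length 128 × 3 channels.
All stochastic steps — generation, initialisation, shuffling, jitter,
mixtures, k-means — derive from explicit integer seeds, and
`run_pipeline()` caches its trained model keyed by a hash of the config
subsections, so re-running an unchanged config reproduces the summary
bit-for-bit.

## Known limitations

* Concept directions are linear; entangled or non-linear concepts (concept
  regions, sparse dictionaries) are out of scope.
* The CAV is frozen during penalty finetuning; iterative refitting during
  training is not implemented.
* LRP rule composites are declared, not derived; other composites (αβ,
  flat) are not provided.
* The annotator oracle is programmatic; no interactive tooling is included.
* Findings on synthetic bundles bound what the mechanisms *can* do, not what
  they achieve on clinical datasets.
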