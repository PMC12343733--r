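# biaslens

Interpretability-driven detection, annotation and unlearning of spurious
shortcuts ("Clever Hans" behaviour) in small convolutional classifiers.

Models trained on observational (e.g. medical-imaging) data often exploit
features that merely *correlate* with the label — a microscope rim around
lesions, a timestamp patch, a scanner's brightness signature, a noisy ECG
lead — and fail the moment the artifact decouples from the label. `biaslens`
implements the full audit-and-revise loop for this failure mode, end to end
on controlled synthetic data, for researchers and students studying shortcut
learning and concept-based model editing:

* **Synthetic study conditions** — 2D image and 1D multichannel signal
  bundles with planted, parameterised artifacts (ring, corner patch, global
  brightness, static noise on one channel), exact insertion rates, ground
  truth masks, and clean/biased test splits.
* **Models + attribution** — a seeded, self-contained CNN engine (2D and 1D)
  splittable at any layer into feature extractor `a_l` and head, with a
  layer-wise relevance propagation (LRP) engine (ε-rule for dense, z⁺ for
  conv, winner-take-all pooling) producing input heatmaps and latent
  relevance tensors.
* **Concept modelling** — concept activation vectors (CAVs): linear-SVM and
  pattern (signal-direction) estimators, single-neuron and
  matrix-decomposition candidates; bias scores `s = hᵀ a_l(x)`.
* **Reveal** — spectral clustering of relevance patterns with Fisher
  separability ranking, concept-distance embeddings, Local Outlier Factor
  scoring, real-sample neuron representation analysis, mixture-model
  prototypes.
* **Annotate** — CAV-based retrieval ranking (AUROC/AP), percentile
  inspection, oracle-in-the-loop iterative label refinement, and
  concept-conditioned localization (`R_l = a_l(x) ∘ h`) with Otsu
  binarisation.
* **Revise** — right-for-the-right-reasons input-gradient penalties, latent
  concept-gradient penalties (exact double-backprop with frozen gates), and
  training-free projection editing `a' = a − ĥ(ĥᵀa − z0)`, plain or
  reactively gated per sample.
* **Re-evaluate** — clean/biased accuracy, artifact relevance, IoU,
  retrieval metrics, and TCAV / ΔTCAV concept sensitivity.

## Worked example

Plant a timestamp-like bright patch in 80% of class-1 training images, train
a small CNN, and audit it:

```r
library(biaslens)

bundle <- generate_image_dataset(60, 32, 2,
                                 artifact_spec("corner_patch", 0.8, 1),
                                 seed = 1)
bundle
#> <dataset_bundle> 2 classes | train 120 (artifact in 48) | val 30 | test 60+60 biased
#>   artifact: corner_patch (p = 0.8, target class 1)

model <- train_model(build_model("cnn2d_small", 2, seed = 1), bundle,
                     train_config(epochs = 12, seed = 1, learning_rate = 5e-3))
accuracy(model, bundle$test_clean)    # 0.817
accuracy(model, bundle$test_biased)   # 0.500
```

The clean-vs-biased gap (0.82 vs 0.50) is the shortcut: on the biased split
every class-2 image also carries the patch and is pulled towards class 1.
Model the artifact as a latent direction and sweep layers for retrieval:

```r
layer_sweep(model, bundle, task = "retrieval")
#>   layer auroc    ap
#> 1 pool1     1     1
#> 2 pool2     1     1
#> 3 pool3     1     1

cav <- paired_artifact_cav(model, bundle, "pool3")
rr  <- rank_samples(cav, model, c(bundle$test_biased, bundle$test_clean))
attr(rr, "auroc")   # 0.999 — held-out artifact retrieval
```

Localize the concept in input space and score it against the ground-truth
mask:

```r
s  <- Filter(function(x) x$artifact_present, bundle$test_biased)[[1]]
lz <- localize_bias(model, s, cav)
iou(lz$binary, s$mask)                    # 0.32
artifact_relevance(lz$soft, s$mask)       # 0.28  (mask covers 0.035 of the image)

tcav_score(model, cav, bundle$test_biased, 1)$delta_tcav   # 0.5 — full reliance
```

The before/after mitigation comparison is packaged as one call
(`mitigation_study(seed = 1)`): it trains a vanilla model on a
brightness-biased bundle, fits a paired-insertion CAV, and reports
clean/biased accuracy and ΔTCAV for the vanilla, penalty-finetuned
(`rr_clarc`) and projection-edited (`p_clarc`, `rp_clarc`) models. A
YAML-driven pipeline (`run_pipeline(pipeline_config(...))`, thin CLI in
`inst/scripts/biaslens`) chains generate → train → reveal → model-the-bias →
evaluate → revise → re-evaluate with on-disk stage outputs.

## Vignette

`vignettes/auditing-shortcut-learning.Rmd` documents the generator's study
conditions, the LRP rule composite, the CAV estimators and their failure
modes, the mitigation losses (including the frozen-gate double-backprop),
the projection-edit invariants, every default parameter with its rationale,
and known limitations.
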