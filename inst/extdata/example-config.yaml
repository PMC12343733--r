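# Example pipeline configuration: corner-patch shortcut on synthetic images,
# audited with a pool3 CAV and revised by projection editing.
dataset:
  type: image
  n_per_class: 40
  image_size: 32
  class_count: 2
  seed: 1
  artifact:
    kind: corner_patch
    insertion_rate_p: 0.8
    target_class: 1
model:
  epochs: 10
  batch_size: 32
  learning_rate: 0.005
  seed: 1
concept:
  layer: pool3
  method: svm
  pooling: max_spatial
revise:
  method: p_clarc
  z0_policy: clean_mean
reveal:
  enabled: false
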