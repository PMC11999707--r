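# Example benchmark configuration: a zero-noise pseudo-slide with three
# planted tumor patches, scored by all attribution methods against the
# color-attentive transformer.
seed: 1
model:
  type: color_attentive
  d: 9
  patch_size: 8
methods: [shapley-exact, rise-binomial, rollout, rollout-res, ig, random]
metrics: [insertion, deletion]
class_index: 2
options:
  rise_n_masks: 1000
  ig_steps: 32
render: true
slides:
  - grid: [3, 3]
    patch_size: 8
    tumor_patches: [1, 5, 9]
    background_patches: [3, 7]
    noise_sd: 0.0
    seed: 11
  - grid: [3, 3]
    patch_size: 8
    tumor_patches: [2, 4]
    background_patches: [6]
    noise_sd: 0.0
    seed: 12
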