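# Demo pipeline: synthetic scenes -> morphometry (on ground-truth masks)
# -> stereology -> slit density -> assays -> statistics.
# Add "train" and "segment" to `stages` for a full run with the learned
# segmenter (several minutes on one CPU).
stages: [generate, morpho, stereo, slit, assay, stats]
n_scenes: 8
n_slit_fields: 6
seed: 1
scene:
  frame_size_px: [256, 256]
  pixels_per_micron: 8.8
  n_glomeruli: 1
  tuft_radius_um: [7, 10]
  nuclei_per_glomerulus: [4, 8]
  nucleus_radius_um: [1.0, 1.5]
  noise_sd: 0.05
exclusion:
  edge_margin_px: 0
  min_area_um2: 50
  max_area_um2: 320
  min_solidity: 0.95
stereo:
  beta: 1.38
  k: 1.0
plan:
  areas_per_glomerulus: 5
  glomeruli_per_mouse_min: 5
stats:
  alpha: 0.05
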