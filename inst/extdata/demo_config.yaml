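# Demo pipeline configuration: one 0.05-degree tile at 0.00025-degree pixels
# (200 x 200), two seasons of 8 synthetic acquisitions each, a 4-labeller
# panel of decreasing skill, and a 2-iteration active-learning run.
seed: 7
out_dir: demo_out
grid:
  pixel_size: 0.00025
fixtures:
  crop_fraction: 0.3
  n_dates_per_season: 8
labelling:
  skills: [1.0, 0.7, 0.6, 0.5]
  n_qa: 4
learning:
  n_starter: 20
  n_validation: 20
  k: 10
  max_iterations: 2
  num_trees: 60
  max_depth: 15
segmentation:
  n_segments: 625
  merge_threshold: 0.05
assessment:
  n_points: 300
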