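# Small end-to-end configuration for `srfmri.R run-all` / run_end_to_end().
# Uses the interpolation-only comparison arm so it finishes in seconds.
seed: 1
n_subjects: 2
sr_mode: lanczos
phantom:
  grid_hr: 64
  n_volumes: 600
  region_a: {semi_x: 5, semi_y: 7, center_y_offset: 0}
  region_b: {semi_x: 5, semi_y: 7, center_y_offset: 0}
  overlap_fraction: 0.3
preprocess:
  n_discard: 30
design:
  tr: 0.5
  n_volumes: 600
  blocks:
    - {task: thumb,  onset: 20,  duration: 15}
    - {task: little, onset: 65,  duration: 15}
    - {task: thumb,  onset: 110, duration: 15}
    - {task: little, onset: 155, duration: 15}
    - {task: thumb,  onset: 200, duration: 15}
    - {task: little, onset: 245, duration: 15}
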