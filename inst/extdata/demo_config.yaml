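structure:
  template:
    sequence: KAAAE
    layout: ladder_line
  n_layers: 10.0
  rise: 4.8
  twist: 0.0
  n_protofilaments: 1
  glycan_length: 8.0
  sulfation: full
  repeat_rise: 8.7
bd:
  n_trajectories: 2000.0
  max_steps: 20000.0
  b_radius: 45.0
  q_radius: 120.0
solvent: []
analysis:
  contact_cutoff: 4.5
  k_clusters: 10.0
  angle_threshold: 45.0
  site_groups: []
  analysis_site: ~
density:
  spacing: 1.0
  padding: 15.0
seed: 1
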