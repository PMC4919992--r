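# Demo pipeline: simulated 3-soil SIP experiment.
# Soils D and F share labelled guild T01-T05; soil W carries the disjoint
# guild T06-T10. Day 18 has weak labelling, day 32 strong labelling.
master_seed: 101
simulate:
  n_taxa: 50
  guild_slots: 10
  n_fractions: 12
  density_min: 1.665
  density_max: 1.775
  band_sigma: 0.006
  seq_depth: 3240
  qpcr_cv: 0.1
  overdispersion: 200
  copy_scale: 1.0e+08
  soils: [D, F, W]
  replicates: 3
  timepoints:
    - days: 18
      label_atom_fraction: 0.05
    - days: 32
      label_atom_fraction: 0.90
  labelled:
    D: [T01, T02, T03, T04, T05]
    F: [T01, T02, T03, T04, T05]
    W: [T06, T07, T08, T09, T10]
detect:
  timepoint: 32
  com_threshold: 0.010
  heavy_k: 2
  min_abund: 0.001
  permutations: 0
  alpha: 0.05
total_shift_tolerance: 0.002
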