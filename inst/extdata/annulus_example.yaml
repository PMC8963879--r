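# Example configuration: inward growth of an annulus-seeded colony.
# Radii and lengths in micrometres; times in division times of strain 1.
geometry:
  type: annulus
  R_in: 20
  R_out: 40
  n_rods: 200
strains:
  - strain_id: 1
    growth_rate: 0.6931471805599453
    division_length: 5
params:
  rng_seed: 1
run:
  t_end: 3
  snapshot_every: 0.5
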