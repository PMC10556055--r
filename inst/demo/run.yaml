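# Demo run: two charged toy monomers, coarse 30-degree landscape grid.
seed: 1729
monomers:
  a:
    type: toy
    n_tm: 12
    label: TOY-A
    ecl_charges:
      - {segment: ECS1, offset: 3, charge: -1}
      - {segment: ECS1, offset: 9, charge: -1}
  b:
    type: toy
    n_tm: 12
    label: TOY-B
    ecl_charges:
      - {segment: ECS1, offset: 5, charge: 1}
landscape:
  increment: 30
  contact_gap: 0.5
  percentile: 10
  window_center: 270
  window_halfwidth: 10
energy:
  sigma: 4.7
  epsilon: 2.0
  dielectric: 15
  cutoff: 12
tetramer:
  gap: 2
  refine: true
pore:
  z_step: 0.5
  probe_threshold: 0.9
residues:
  cutoff: 6
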