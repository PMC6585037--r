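# End-to-end pipeline configuration for the packaged TOY-B network.
# Defaults mirror the published settings where stated (epsilon = 1e-4,
# filter fractions 0.01 / 0.90); evaluation budgets are scaled to toy size.
model: TOY-B
product: R_p
substrate: R_s
atpm: R_m
seed: 1
environment:
  R_s: [0, 10]
filter:
  min_growth_fraction_of_wt: 0.01
  coupling_growth_fraction: 0.90
formulations:
  MCSw:
    eps: 1.0e-4
    F: 0.1
    max_size: 3
    min_biomass: 1.0e-4
  EAm:
    max_evaluations: 500
    max_knockouts: 3
    pop_size: 20
    archive_size: 10
    runs: 3
analysis:
  carbon:
    R_p: 4
    R_s: 6
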