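# Tri-culture chemostat preset: 650 ml vessel fed at 0.34 ml/min
# (D ~ 0.03 1/h), 30 C, nitrogen-sparged headspace.
reactor:
  working_volume_ml: 650
  feed_flow_ml_min: 0.34
  headspace_gas_flow_ml_min: 49
  temperature_C: 30
  feed_mM:
    cellobiose: 2.2
    fumarate: 4.9
    sulfate: 8
    NaHCO3: 5
assays:
  - species: C. cellulolyticum
    rrn_copies_per_genome: 8
    genome_size_bp: 4070000
    primer_pair: Clos-F/Clos-R
  - species: D. vulgaris
    rrn_copies_per_genome: 5
    genome_size_bp: 3570000
    primer_pair: DvH-F/DvH-R
  - species: G. sulfurreducens
    rrn_copies_per_genome: 2
    genome_size_bp: 3810000
    primer_pair: Geo-F/Geo-R
splits:
  geobacter_acetate_uptake: 0.45
  geobacter_acetate_oxidized: 0.3
  h2_fraction_of_donor_pool: 0.5
noise:
  conc_sd_rel: 0.05
  conc_sd_abs_mM: 0.02
  od_sd: 0.01
  cq_sd: 0.1
  bio_cv: 0.05
  detection_limits_mM:
    hydrogen: 0.0003
# measured steady-state cell counts (qPCR), cells/ml
counts_cells_per_ml:
  C. cellulolyticum: 460.0e+6
  D. vulgaris: 29.0e+6
  G. sulfurreducens: 36.0e+6
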