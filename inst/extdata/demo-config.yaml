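# Demonstration pipeline configuration: two small simulated cohorts with the
# qualitative signature of a cell-production mutant (fewer, longer mature
# cells at similar cell-cycle duration), plus a matching ploidy experiment.
# Positions in um, rates per hour.
seed: 1
cohorts:
  - name: WT
    n_roots: 3
    spec:
      meristem_length: 500
      initial_cell_length: 10
      meristem_strain_rate: 0.04
      elongation_zone_length: 400
      elongation_strain_integral: 280
      bump_shape: raised_cosine
  - name: mutant
    n_roots: 3
    spec:
      meristem_length: 375
      initial_cell_length: 10
      meristem_strain_rate: 0.04
      elongation_zone_length: 400
      elongation_strain_integral: 255
      bump_shape: raised_cosine
particles:
  n_per_root: 40
  dt: 1
  position_noise_sd: 5
cell_files:
  length_cv: 0.05
  qc_offset: 0
ploidy_sim:
  n_nuclei: 2000
  anchor: 100
  cv: 0.05
  samples_per_group: 3
  proportions:
    WT: {2C: 0.45, 4C: 0.33, 8C: 0.14, 16C: 0.05, 32C: 0.03}
    mutant: {2C: 0.38, 4C: 0.30, 8C: 0.16, 16C: 0.12, 32C: 0.04}
static_profile:
  tol: 0.05
  median_filter: false
kinematics:
  bandwidth: 50
  grid_step: 1
  plateau_frac: 0.95
ploidy:
  anchor: null
compare:
  metrics: [P_cells_per_h, mature_len_um]
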