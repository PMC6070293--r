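# Reference exploratory-dynamics run: mating-cell mesh, default rate
# constants, 600 s of simulated time. Usable directly:
#   run_scenario(system.file("extdata/reference_exploration.yaml",
#                            package = "ras1zone"))
name: reference_exploration
mesh:
  radius: 2.0
  tip_to_tip_length: 6.0
  n_axial: 45
  n_circ: 40
params: {}
duration: 600
seed: 1
sample_stride: 1
analyses: [period, classify]
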