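name: pancreas_ptt
phantom:
  kind: cube
  world_volume_cm3: 4
  pitch_mm: 0.25
  base_material: pancreas
  tumor:
    volume_cm3: 3
    center: [0, 0, 0]
    material: tumor_gnr
    clip: true
materials: default
gnr:
  diameter_nm: 10
  length_nm: 41
  mass_concentration: 12.5
  bulk_gold_density: 19.3
  particle_eps: table
  host_eps_re: 1.767
  host_eps_im: 0
  nano_mu_a: computed
laser:
  wavelength_nm: 808
  power_w: 2.1
  tip_diameter_mm: 0.3
  tip_position_mm: [0, 0, 0]
  direction: [0, 0, 1]
  emission_rate: 2.0e+6
  duration_s: 120
  area_unit: mm2
transport:
  n_histories: 2.0e+6
  max_steps: 1.0e+6
heat:
  model: auto
  alpha_mm2_s: 0.16
  dt_s: 1
  baseline_c: 26
  perfusion: false
schedule: [10, 20, 30, 40, 60, 85, 120]
probes:
  - position_mm: [0, 2, 0]
    mode: hd
  - position_mm: [0, 0, 2]
    mode: vd
threshold_c: 155
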