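name: water_drop_gnr
phantom:
  kind: cylinder_drop
  world_volume_cm3: 4.096
  pitch_mm: 0.1
  base_material: air
  drop:
    material: water
    radius_mm: 7.75
    z_range: [-0.53, 0]
materials: default
gnr:
  diameter_nm: 10
  length_nm: 41
  mass_concentration: 625
  bulk_gold_density: 19.3
  particle_eps: drude
  host_eps_re: 1.769
  host_eps_im: 0
  nano_mu_a: computed
laser:
  wavelength_nm: 808
  power_w: 2.1
  tip_diameter_mm: 3
  tip_position_mm: [0, 0, -1.0e-6]
  direction: [0, 0, -1]
  emission_rate: 2.0e+6
  duration_s: 30
  area_unit: mm2
transport:
  n_histories: 2.0e+5
  max_steps: 1.0e+6
heat:
  model: auto
  alpha_mm2_s: 0.143
  dt_s: 1
  baseline_c: 26
  perfusion: false
schedule: [10, 20, 30]
probes:
  - position_mm: [0, 0, -0.05]
    mode: vd
threshold_c: 155
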