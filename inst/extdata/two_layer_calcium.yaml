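# Demo: interleaved two-slab props acquisition of a two-layer calcium phantom
seed: 7
phantom:
  type: two_layer_calcium
  shape_zyx: [64, 24, 48]
  voxel_um: [1, 1, 1]
  layer_z_um: [15, 55]
  n_cells: 3
  cell_sigma_um: 2
  amplitude: 0.5
  duration_s: 1.2
  frame_interval_s: 0.02
acquisition:
  optics:
    tilt_phi_deg: 45
    sheet_sigma_um: 0
    pixel_pitch_um: 1
    z_max_um: 64
  sweep:
    s_range_um: [-70, 60]
    duration_s: 0.01
  shear:
    rate: 1.4142136
  shutter:
    width_um: 17.0
    center_um: 21.2132
  # delays realizing slab centers 15 um and 55 um (row speed = rate * v_s)
  delays_s: [0.0, 0.0030769]
analysis:
  dff_baseline_percentile: 20
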