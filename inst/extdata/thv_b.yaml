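schema: thvforge-valve/1
name: THV-B
profile:
  phi_max: 15.0
  points:
    - {r: 13.00, phi: 0.0, z: 0.0}
    - {r: 13.00, phi: 15.0, z: 3.65}
    - {r: 13.00, phi: 0.0, z: 6.70}
    - {r: 13.00, phi: 15.0, z: 9.70}
    - {r: 13.00, phi: 0.0, z: 12.75}
    - {r: 13.00, phi: 15.0, z: 15.20}
    - {r: 13.00, phi: 0.0, z: 17.60}
    - {r: 13.00, phi: 15.0, z: 20.05}
support:
  end_fraction: 0.25
  interior_fraction: 0.125
skirt:
  approximated_from_figure: true
  vertical:
    - {ref: P1}
    - {ref: P2, transforms: [{op: rotate_z, angle: -15.0}]}
    - {ref: P3}
    - {ref: P4, transforms: [{op: rotate_z, angle: -15.0}]}
    - {ref: P5}
    - {ref: P6, transforms: [{op: rotate_z, angle: -15.0}]}
    - {ref: P7}
    - {ref: P8, transforms: [{op: rotate_z, angle: -15.0}]}
  bottom:
    - {ref: P1}
    - {ref: P1, transforms: [{op: rotate_z, angle: 15.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 30.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 45.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 60.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 75.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 90.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 105.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 120.0}]}
  top:
    - {ref: P8, transforms: [{op: rotate_z, angle: -15.0}]}
    - {ref: P8}
    - {ref: P8, transforms: [{op: rotate_z, angle: 15.0}]}
    - {ref: P8, transforms: [{op: rotate_z, angle: 30.0}]}
    - {ref: P8, transforms: [{op: rotate_z, angle: 45.0}]}
    - {ref: P8, transforms: [{op: rotate_z, angle: 60.0}]}
    - {ref: P8, transforms: [{op: rotate_z, angle: 75.0}]}
    - {ref: P8, transforms: [{op: rotate_z, angle: 90.0}]}
    - {ref: P8, transforms: [{op: rotate_z, angle: 105.0}]}
commissure:
  central:
    - {ref: P7}
    - {ref: P7, support: above}
    - {ref: P8, transforms: [{op: rotate_z, angle: -15.0}]}
  edge_source: central_curve
leaflet:
  approximated_from_figure: true
  upper_translation: 0.15
  upper_span: [0.0, 1.0]
  lower_edge:
    - {ref: upper_edge_bottom}
    - {ref: P5, transforms: [{op: rotate_z, angle: 15.0}]}
    - {ref: P3, transforms: [{op: rotate_z, angle: 30.0}]}
  attachment:
    - {ref: P3, transforms: [{op: rotate_z, angle: 30.0}]}
    - {ref: P2, transforms: [{op: rotate_z, angle: 30.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 60.0}, {op: offset, vertical: 2.0}]}
  free_edge:
    mode: center_flat
    side_fractions: [0.25, 0.5]
    near_axis_vertical_offset: 0.0
    center_radial_offset: 1.5
    center_vertical_offset: 0.0
  belly:
    radial_offset: 5.0
    vertical_offset: -10.0
  interior_factor: 1.0
  use_arc: false
materials:
  frame: {youngs_modulus_gpa: 58.0, poisson: 0.33, density_g_cm3: 6.45}
  leaflet: {c0_kpa: 117.1375, c1_kpa: 41.4347, c2: 109.7423, c3: 132.4545, w: 0.9883, fiber_angle_deg: 45.0}
  skirt: {c0_kpa: 117.1375, c1_kpa: 60.3991, c2: 92.4784, w: 1.0}
  shell: {thickness_cm: 0.033, density_g_cm3: 1.0}
  penalty: {alpha_ss: 1000.0, alpha_sb: 10000.0, alpha_f: 1.0e+11, mu_friction: 0.2}
  beam_section_mm: [0.54, 0.21]
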