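schema: thvforge-valve/1
name: THV-A
profile:
  phi_max: 12.0
  points:
    - {r: 13.15, phi: 0.0, z: 0.0}
    - {r: 12.55, phi: 12.0, z: 5.0}
    - {r: 12.20, phi: 0.0, z: 9.0}
    - {r: 11.75, phi: 12.0, z: 13.0}
    - {r: 11.55, phi: 0.0, z: 16.5}
    - {r: 11.00, phi: 12.0, z: 20.0}
    - {r: 11.00, phi: 0.0, z: 23.5}
    - {r: 12.65, phi: 12.0, z: 27.5}
    - {r: 15.20, phi: 0.0, z: 32.5}
    - {r: 15.85, phi: 12.0, z: 38.5}
    - {r: 14.90, phi: 0.0, z: 45.0}
support:
  end_fraction: 0.25
  interior_fraction: 0.125
skirt:
  approximated_from_figure: true
  vertical:
    - {ref: P1}
    - {ref: P2, transforms: [{op: rotate_z, angle: -12.0}]}
    - {ref: P3}
    - {ref: P4, transforms: [{op: rotate_z, angle: -12.0}]}
    - {ref: P5}
    - {ref: P6, transforms: [{op: rotate_z, angle: -12.0}]}
    - {ref: P7}
  bottom:
    - {ref: P1}
    - {ref: P1, transforms: [{op: rotate_z, angle: 12.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 24.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 36.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 48.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 60.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 72.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 84.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 96.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 108.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 120.0}]}
  top:
    - {ref: P7}
    - {ref: P7, transforms: [{op: rotate_z, angle: 12.0}]}
    - {ref: P7, transforms: [{op: rotate_z, angle: 24.0}]}
    - {ref: P7, transforms: [{op: rotate_z, angle: 36.0}]}
    - {ref: P7, transforms: [{op: rotate_z, angle: 48.0}]}
    - {ref: P7, transforms: [{op: rotate_z, angle: 60.0}]}
    - {ref: P7, transforms: [{op: rotate_z, angle: 72.0}]}
    - {ref: P7, transforms: [{op: rotate_z, angle: 84.0}]}
    - {ref: P7, transforms: [{op: rotate_z, angle: 96.0}]}
    - {ref: P7, transforms: [{op: rotate_z, angle: 108.0}]}
    - {ref: P7, transforms: [{op: rotate_z, angle: 120.0}]}
commissure:
  central:
    - {ref: P7}
    - {ref: P7, support: above}
    - {ref: P8, transforms: [{op: rotate_z, angle: -12.0}]}
    - {ref: P9, support: below}
    - {ref: P9}
  edge_source: central_curve
leaflet:
  approximated_from_figure: true
  upper_translation: 0.12
  upper_span: [0.0, 1.0]
  lower_edge:
    - {ref: upper_edge_bottom}
    - {ref: P6}
    - {ref: P5, transforms: [{op: rotate_z, angle: 18.0}]}
    - {ref: P3, transforms: [{op: rotate_z, angle: 36.0}]}
  attachment:
    - {ref: P3, transforms: [{op: rotate_z, angle: 36.0}]}
    - {ref: P2, transforms: [{op: rotate_z, angle: 36.0}]}
    - {ref: P1, transforms: [{op: rotate_z, angle: 60.0}, {op: offset, radial: -1.15, vertical: 3.5}]}
  free_edge:
    mode: center_low
    side_fractions: [0.25, 0.5]
    near_axis_vertical_offset: 0.0
    center_radial_offset: 1.5
    center_vertical_offset: -6.0
  belly:
    radial_offset: 5.0
    vertical_offset: -20.5
  interior_factor: 1.0
  use_arc: true
materials:
  frame: {youngs_modulus_gpa: 58.0, poisson: 0.33, density_g_cm3: 6.45}
  leaflet: {c0_kpa: 117.1375, c1_kpa: 41.4347, c2: 109.7423, c3: 132.4545, w: 0.9883, fiber_angle_deg: 45.0}
  skirt: {c0_kpa: 117.1375, c1_kpa: 60.3991, c2: 92.4784, w: 1.0}
  shell: {thickness_cm: 0.033, density_g_cm3: 1.0}
  penalty: {alpha_ss: 1000.0, alpha_sb: 10000.0, alpha_f: 1.0e+11, mu_friction: 0.2}
  beam_section_mm: [0.54, 0.21]
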