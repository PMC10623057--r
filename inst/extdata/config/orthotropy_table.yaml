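# Chevron ERR across orthotropy ratios eta = E_x/E_y and arm angles.
protocol: orthotropy_table
incision: {family: chevron, length_mm: 2.2, angle_deg: 170}
material: {E_MPa: 9.82, nu: 0.49, Gc_kJ_m2: 5.40}
load: {d_target_mm: 1.73}
orthotropy:
  etas: [2, 1.5, 1, 0.75, 0.5]
  alphas_deg: [165, 170, 175, 180]
output_dir: orthotropy
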