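# Chevron arm-angle sweep at fixed 2.2 mm incision length, each angle at its
# own load calibrated to the 1.73 mm injector opening.
protocol: sweep_chevron
incision: {family: chevron, length_mm: 2.2, angle_deg: 150}
material: {E_MPa: 9.82, nu: 0.49, Gc_kJ_m2: 5.40}
load: {d_target_mm: 1.73}
sweep:
  alphas_deg: [120, 125, 130, 135, 140, 145, 150, 155, 160, 165, 170, 175, 180]
  refine: true
output_dir: chevron-sweep
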