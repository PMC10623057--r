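# Frown central-angle sweep at fixed 2.2 mm arclength, calibrated loads.
protocol: sweep_frown
incision: {family: frown, length_mm: 2.2, angle_deg: 35}
material: {E_MPa: 9.82, nu: 0.49, Gc_kJ_m2: 5.40}
load: {d_target_mm: 1.73}
sweep:
  betas_deg: [5, 10, 15, 20, 25, 30, 35, 40, 45, 50]
  refine: true
output_dir: frown-sweep
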