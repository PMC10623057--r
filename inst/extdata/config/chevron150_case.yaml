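# Single chevron case at the 150-degree arm angle under a calibrated load,
# with VTK export of the displacement and von Mises fields.
protocol: case
incision: {family: chevron, length_mm: 2.2, angle_deg: 150}
material: {E_MPa: 9.82, nu: 0.49, Gc_kJ_m2: 5.40}
load: {d_target_mm: 1.73}
export: {vtk: true, figures: false}
output_dir: chevron150
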