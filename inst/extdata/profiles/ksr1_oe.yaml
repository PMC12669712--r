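# Scaffold-overexpressing MEF condition: elevated nuclear and cytoplasmic
# target protein, shorter actin fibers, wild-type-like nuclear geometry.
condition_name: KSR1_oe
cells_per_image: 9
nucleus_radius_mean: 16
nucleus_radius_sd: 1.5
nucleus_axis_ratio_mean: 0.85
nucleus_displacement_frac_mean: 0.05
yap_nuclear_mean: 270
yap_cyto_mean: 130
fiber_count_mean: 3
fiber_length_mean: 20
fiber_length_sd: 4
background_level: 20
noise_sd: 6
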