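# Scaffold-knockout MEF condition. Nuclear target-protein intensity is
# 0.62 x wild type (a 38% reduction); nuclei are smaller, more elongated
# (lower minor/major ratio) and more displaced from the cell centroid, and
# actin fibers are longer.
condition_name: KSR1_null
cells_per_image: 9
nucleus_radius_mean: 13.5
nucleus_radius_sd: 1.5
nucleus_axis_ratio_mean: 0.70
nucleus_displacement_frac_mean: 0.15
yap_nuclear_mean: 111.6
yap_cyto_mean: 95
fiber_count_mean: 4
fiber_length_mean: 42
fiber_length_sd: 7
background_level: 20
noise_sd: 6
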