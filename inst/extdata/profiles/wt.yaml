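# Wild-type MEF condition. Intensities are arbitrary units; what matters is
# the ratio of channel means between this profile and the others.
condition_name: WT
cells_per_image: 9
nucleus_radius_mean: 16
nucleus_radius_sd: 1.5
nucleus_axis_ratio_mean: 0.85
nucleus_displacement_frac_mean: 0.05
yap_nuclear_mean: 180
yap_cyto_mean: 80
fiber_count_mean: 4
fiber_length_mean: 28
fiber_length_sd: 5
background_level: 20
noise_sd: 6
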