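# YAP hnRNA in MCF-7 cells, scaffold siRNA knockdown vs control siRNA:
# 51% reduction (true fold change 0.49), GAPDH reference.
genes: [YAP, GAPDH]
reference_gene: GAPDH
conditions: [siCtrl, siKSR1]
calibrator_condition: siCtrl
true_fold_change:
  YAP: {siCtrl: 1.0, siKSR1: 0.49}
  GAPDH: {siCtrl: 1.0, siKSR1: 1.0}
reference_ct_mean: 20
replicates: 3
runs: 3
ct_noise_sd: 0.15
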