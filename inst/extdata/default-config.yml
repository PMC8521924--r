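# Default pipeline configuration for the eegsweep CLI (flat key-value YAML).
# Flags given on the command line override these values.
n_epochs: 1000
n_channels: 8
fs: 200
epoch_len: 1
n_classes: 6
prevalence: 0.172
magnitude_min: 5
magnitude_max: 10
n_subjects: 1
subject_heterogeneity: 0
method: lscp
contamination: 0.172
mode: aggregated
h: 32
gap: 40
pairs_per_epoch: 1
train_epochs: 200
workers: 1
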