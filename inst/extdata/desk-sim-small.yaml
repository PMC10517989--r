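# Reduced desk-scale simulation study: same physics, smaller scene and
# counts, for quick smoke runs of the CLI and drivers.
preset: desk-sim
grid_extent: [0.049, 0.049]
grid_n: [12, 12]
n_train: 12
n_test: 4
epochs: 2
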