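# Flat key: value config consumed by the bioagesim CLI (see read_config()).
seed: 42
replicates: 5
n_draws: 200
generator: example2
scenario: D
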