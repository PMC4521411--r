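# Seven-day citrate-silver / DPPC lipid-solution incubation
scenario: leo2013
enm_spec: L20
n_particles: 100
seed: 1
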