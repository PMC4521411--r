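# Human alveolar lining layer, single-breath inhalation exposure
scenario: invivo_human
enm_spec: C20
n_particles: 100
seed: 1
n_replicates: 10
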