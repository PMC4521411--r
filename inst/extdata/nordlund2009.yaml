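# One-hour stirred silica / DOPC vesicle incubation
scenario: nordlund2009
enm_spec: N600
n_particles: 100
seed: 1
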