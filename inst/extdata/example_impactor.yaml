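device: HandiHaler
flow_lpm: 60.0
duration_s: 60.0
loaded_mass: 10.0
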