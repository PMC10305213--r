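# Human airway diameter bands for passive inhalation (Weibel generation
# annotation); mass above 10 um is residual (extrathoracic/not deposited).
species: human
mode: passive
regions:
  - {name: alveoli, lo_um: 0, hi_um: 2, generations: "17-23"}
  - {name: bronchioles, lo_um: 2, hi_um: 5, generations: "5-17"}
  - {name: bronchi, lo_um: 5, hi_um: 7, generations: "1-4"}
  - {name: trachea, lo_um: 7, hi_um: 10, generations: "0"}
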