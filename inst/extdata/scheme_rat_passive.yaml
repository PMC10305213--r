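# Rat airway diameter bands for passive inhalation. Rats are obligate nose
# breathers; the nose filters particles above ~3 um (inhalability cutoff).
species: rat
mode: passive
inhalability_cutoff_um: 3
regions:
  - {name: alveoli, lo_um: 0, hi_um: 1, generations: "17-23"}
  - {name: bronchioles, lo_um: 1, hi_um: 2, generations: "5-17"}
  - {name: bronchi, lo_um: 2, hi_um: 3, generations: "1-4"}
  - {name: trachea, lo_um: 3, hi_um: null, generations: "0"}
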