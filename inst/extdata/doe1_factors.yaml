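# Factor declaration for doe1.csv (actual low/high settings per factor).
factors:
  - {name: feed_conc, low: 0.25, high: 0.35, units: "% w/v"}
  - {name: n2_flow, low: 600, high: 742, units: "L/h"}
  - {name: aspiration, low: 20, high: 30, units: "m^3/min"}
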