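# Next-generation impactor: archival stage D50 cutoffs at the 60 L/min
# reference flow with square-root flow scaling per stage.
name: NGI (archival calibration, 60 L/min reference)
ref_flow_lpm: 60
flow_range_lpm: [10, 100]
stages:
  - {stage: 1, cutoff_um_at_ref: 8.06, scaling_exponent: 0.5}
  - {stage: 2, cutoff_um_at_ref: 4.46, scaling_exponent: 0.5}
  - {stage: 3, cutoff_um_at_ref: 2.82, scaling_exponent: 0.5}
  - {stage: 4, cutoff_um_at_ref: 1.66, scaling_exponent: 0.5}
  - {stage: 5, cutoff_um_at_ref: 0.94, scaling_exponent: 0.5}
  - {stage: 6, cutoff_um_at_ref: 0.55, scaling_exponent: 0.5}
  - {stage: 7, cutoff_um_at_ref: 0.34, scaling_exponent: 0.5}
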