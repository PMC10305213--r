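# 2^2 full factorial, spray-drying refinement round: aspiration rate
# (m^3/min), feed flow rate (mL/min); responses as in doe1.csv.
run,aspiration,feed_rate,dg,gsd_dg,dv,gsd_dv
1,30,3.0,2.55,1.64,5.25,1.20
2,35,3.0,2.35,1.56,5.07,1.15
3,35,7.5,2.30,1.68,5.10,1.15
4,30,7.5,2.70,1.78,5.26,1.16
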