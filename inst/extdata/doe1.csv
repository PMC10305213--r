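# 2^3 full factorial, spray-drying screening round: feed concentration
# (% w/v), N2 flow rate (L/h), aspiration rate (m^3/min); responses are the
# geometric and volume diameters (um) and their GSDs per batch.
run,feed_conc,n2_flow,aspiration,dg,gsd_dg,dv,gsd_dv
1,0.25,742,30,2.70,1.54,5.40,1.16
2,0.35,742,30,2.85,1.48,5.47,1.17
3,0.25,600,20,3.50,1.67,5.68,1.20
4,0.35,742,20,3.00,1.68,5.43,1.16
5,0.35,600,20,3.10,1.75,5.57,1.18
6,0.25,742,20,3.30,1.94,5.63,1.18
7,0.35,600,30,3.70,1.60,5.39,1.15
8,0.25,600,30,3.15,1.62,5.51,1.18
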