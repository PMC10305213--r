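# Synthetic example: exact lognormal cumulative-undersize values (median 2.30 um,
# GSD 1.65) with a saturated 100% row; for read_sizing_csv()/fit_lognormal() demos.
diameter_um,cumulative_percent_undersize
0.8,1.75
1.2,9.69
1.8,31.22
2.3,50
3,70.21
4,86.54
5.5,95.92
12,100
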