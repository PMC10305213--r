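# Synthetic example impactor run (ideal NGI collection, 3% multiplicative noise,
# true MMAD 2.5 um / GSD 1.7, ED 75%, port fraction 0.25); metadata in example_impactor.yaml.
surface,mass
induction_port,1.79731
stage_1,0.07706
stage_2,0.69641
stage_3,1.62831
stage_4,2.03724
stage_5,1.09824
stage_6,0.17823
stage_7,0.01119
moc,0.00046
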