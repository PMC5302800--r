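# temperature_K: 348.15
metabolite	mu0_kJ_mol	dg_kJ_mol
hv	68.6	0.0000000000
h2o	0.0	0.0000000000
co2	-25.0	19.9946295931
no3	-20.0	19.9946295931
nh3	-30.0	19.9946295931
ac	50.0	19.9946295931
glyc	40.0	19.9946295931
so4	-40.0	19.9946295931
h2s	20.0	19.9946295931
glc	3142.8	19.9946295931
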