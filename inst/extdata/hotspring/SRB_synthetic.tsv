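# id: SRB
[METABOLITES]
id	name	compartment	external	mu0	conc_lo	conc_hi
ac	ac	SRB	TRUE			
nh3	nh3	SRB	TRUE			
so4	so4	SRB	TRUE			
h2s	h2s	SRB	TRUE			
[REACTIONS]
id	formula	lb	ub	kind	objective
BIO_SRB	1 ac + 0.830769230769 nh3 + 0.5 so4 -> 0.5 h2s	0	1000	biomass	1
EX_ac	1 ac -> 	-1	0	exchange	0
EX_nh3	1 nh3 -> 	-10	0	exchange	0
EX_so4	1 so4 -> 	-10	0	exchange	0
EX_h2s	1 h2s -> 	0	1000	exchange	0
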