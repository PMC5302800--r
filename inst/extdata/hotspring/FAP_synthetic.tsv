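# id: FAP
[METABOLITES]
id	name	compartment	external	mu0	conc_lo	conc_hi
ph	ph	FAP	FALSE			
chx	chx	FAP	FALSE			
hv	hv	FAP	TRUE			
co2	co2	FAP	TRUE			
nh3	nh3	FAP	TRUE			
ac	ac	FAP	TRUE			
glyc	glyc	FAP	TRUE			
[REACTIONS]
id	formula	lb	ub	kind	objective
PSB	1 hv -> 1 ph	0	1000	internal	0
CFX	1 co2 -> 1 chx	0	1000	internal	0
ACU	1 ac -> 1 chx	0	1000	internal	0
GLU	1 glyc -> 1 chx	-1000	1000	internal	0
RSP	1 chx -> 1 co2	0	1000	internal	0
BIO_FAP	1 ph + 0.760869565217 chx + 1 nh3 -> 	0	1000	biomass	1
EX_hv	1 hv -> 	-1	0	exchange	0
EX_co2	1 co2 -> 	-2	1000	exchange	0
EX_nh3	1 nh3 -> 	-10	0	exchange	0
EX_ac	1 ac -> 	-2	0	exchange	0
EX_glyc	1 glyc -> 	-10	1000	exchange	0
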