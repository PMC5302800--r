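# id: SYN
[METABOLITES]
id	name	compartment	external	mu0	conc_lo	conc_hi
ph	ph	SYN	FALSE			
chx	chx	SYN	FALSE			
nh3i	nh3i	SYN	FALSE			
hv	hv	SYN	TRUE			
h2o	h2o	SYN	TRUE			
co2	co2	SYN	TRUE			
no3	no3	SYN	TRUE			
nh3	nh3	SYN	TRUE			
ac	ac	SYN	TRUE			
glyc	glyc	SYN	TRUE			
[REACTIONS]
id	formula	lb	ub	kind	objective
PSII	1 hv + 1 h2o -> 1 ph	0	1000	internal	0
RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN	1 co2 -> 1 chx	0	1000	internal	0
RXN-961	1 chx -> 1 glyc	0	1000	internal	0
NAR	1 no3 -> 1 nh3i	0	1000	internal	0
AMT	1 nh3 -> 1 nh3i	-1000	1000	internal	0
ACS	0.820224719101 ph + 1 chx -> 1 ac	0	1000	internal	0
BIO_SYN	1 ph + 0.407407407407 chx + 0.965242165242 nh3i -> 	0	1000	biomass	1
EX_hv	1 hv -> 	-1	0	exchange	0
EX_h2o	1 h2o -> 	-1000	1000	exchange	0
EX_co2	1 co2 -> 	-2	1000	exchange	0
EX_no3	1 no3 -> 	-10	1000	exchange	0
EX_nh3	1 nh3 -> 	-10	1000	exchange	0
EX_ac	1 ac -> 	0	1000	exchange	0
EX_glyc	1 glyc -> 	0	1000	exchange	0
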