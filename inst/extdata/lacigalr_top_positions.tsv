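position	domain	ccpa	galrs	gntr	purr	rbsra	trer	contact
7	D	0	1	0	0	0	0	DNA
25	D	0	0	0	0	0	1	DNA
31	D	0	0	1	0	0	0	DNA
32	D	1	0	0	0	0	0	
34	D	0	0	1	0	0	0	DNA
42	D	0	1	0	0	0	1	
51	L	0	0	0	0	0	1	dimer_interface
54	L	0	1	0	0	0	1	DNA
66	R	0	0	0	1	0	0	
68	R	0	0	0	1	0	0	
79	R	0	0	0	0	1	0	ligand
84	R	1	0	0	0	0	0	dimer_interface
95	R	1	0	0	0	1	0	dimer_interface
97	R	0	0	0	1	0	0	dimer_interface
99	R	0	1	0	0	0	0	
113	R	0	1	0	0	0	0	dimer_interface
114	R	0	0	0	1	0	0	
115	R	1	0	0	0	0	0	dimer_interface
117	R	0	1	0	0	0	0	dimer_interface
125	R	0	0	0	0	1	0	ligand
127	R	0	0	1	0	0	0	
143	R	1	0	0	0	0	0	
147	R	0	0	0	0	1	0	
154	R	0	0	1	0	0	0	
158	R	0	0	0	0	1	0	
163	R	0	1	1	0	0	1	
168	R	0	0	0	0	1	0	
171	R	0	0	1	1	0	0	
191	R	0	0	0	1	0	0	ligand
207	R	0	0	0	0	1	0	
214	R	0	1	0	0	1	0	
218	R	0	0	0	0	0	1	
222	R	0	0	1	1	1	0	dimer_interface
224	R	0	0	0	0	0	1	
225	R	0	0	0	0	0	1	
228	R	1	0	0	0	0	0	
239	R	1	0	0	0	0	0	
246	R	0	0	0	1	0	0	ligand
249	R	1	0	0	0	0	0	
254	R	0	0	0	0	1	0	
255	R	1	0	0	1	0	0	dimer_interface
256	R	0	0	0	0	0	1	
274	R	0	0	1	0	0	0	ligand
275	R	0	0	1	0	0	0	
276	R	0	0	1	0	0	0	
277	R	0	1	0	0	0	0	dimer_interface
283	R	0	0	0	0	0	1	dimer_interface
285	R	0	0	0	1	0	0	dimer_interface
303	R	1	0	0	0	0	0	partner_protein
307	R	0	1	0	0	0	0	
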