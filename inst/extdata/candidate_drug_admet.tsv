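compound	caco2	hia	pgp_inhibitor	logbb	logps	cyp3a4_inhibitor	total_clearance	ames	lc50	ld50
Digoxin	0.59	68.58	yes	-1.39	-3.81	no	3.67	no	4.35	3.7
Imatinib	1.09	93.85	yes	-1.37	-2.51	yes	0.72	no	2.08	2.9
Dovitinib	0.47	83.63	no	-0.71	-2.27	yes	0.76	yes	3.04	2.4
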