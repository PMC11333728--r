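compound	mw	logp	hba	hbd	psa	rotatable_bonds
Digoxin	780	4.84	14	6	203.06	7
Imatinib	493	4.04	6	2	86.28	8
Dovitinib	393.43	2.26	4	3	94.04	2
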