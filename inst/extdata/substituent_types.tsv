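name	label	mode	dC	dH	dN	dO	dS	dP	aC	aH	aN	aO
n-acetyl	NAc	d	2	3	1	0	0	0	2	2	0	1
n-glycolyl	NGc	d	2	3	1	1	0	0	2	2	0	2
amino	N	d	0	1	1	-1	0	0	-	-	-	-
acetyl	Ac	o	2	2	0	1	0	0	-	-	-	-
methyl	Me	o	1	2	0	0	0	0	-	-	-	-
sulfate	S	o	0	0	0	3	1	0	-	-	-	-
phosphate	P	o	0	1	0	3	0	1	-	-	-	-
pyruvate	Pyr	o	3	2	0	2	0	0	-	-	-	-
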