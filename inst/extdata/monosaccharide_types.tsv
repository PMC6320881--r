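name	superclass	carbon_count	anomeric_carbon	snfg_shape	snfg_color	default_config	default_ring	stereo	mods	amine_position
Glc	HEX	6	1	circle	blue	D	p	dglc	-	-
Man	HEX	6	1	circle	green	D	p	dman	-	-
Gal	HEX	6	1	circle	yellow	D	p	dgal	-	-
Gul	HEX	6	1	circle	orange	D	p	dgul	-	-
Alt	HEX	6	1	circle	pink	D	p	dalt	-	-
All	HEX	6	1	circle	purple	D	p	dall	-	-
Tal	HEX	6	1	circle	light_blue	D	p	dtal	-	-
Ido	HEX	6	1	circle	brown	D	p	dido	-	-
GlcN	HEX	6	1	crossed-square	blue	D	p	dglc	-	2
ManN	HEX	6	1	crossed-square	green	D	p	dman	-	2
GalN	HEX	6	1	crossed-square	yellow	D	p	dgal	-	2
GlcA	HEX	6	1	divided-diamond	blue	D	p	dglc	6:a	-
ManA	HEX	6	1	divided-diamond	green	D	p	dman	6:a	-
GalA	HEX	6	1	divided-diamond	yellow	D	p	dgal	6:a	-
IdoA	HEX	6	1	divided-diamond	brown	L	p	lido	6:a	-
Fuc	HEX	6	1	triangle	red	L	p	lgal	6:d	-
Qui	HEX	6	1	triangle	blue	D	p	dglc	6:d	-
Rha	HEX	6	1	triangle	green	L	p	lman	6:d	-
Xyl	PEN	5	1	star	orange	D	p	dxyl	-	-
Ara	PEN	5	1	star	green	L	p	lara	-	-
Rib	PEN	5	1	star	pink	D	f	drib	-	-
Lyx	PEN	5	1	star	yellow	D	p	dlyx	-	-
Kdn	NON	9	2	diamond	green	D	p	dgro-dgal	1:a,2:keto,3:d	-
Neu	NON	9	2	diamond	brown	D	p	dgro-dgal	1:a,2:keto,3:d	5
Fru	HEX	6	2	pentagon	green	D	f	dara	2:keto	-
LDmanHep	HEP	7	1	hexagon	green	D	p	lgro-dman	-	-
Kdo	OCT	8	2	hexagon	yellow	D	p	dman	1:a,2:keto,3:d	-
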