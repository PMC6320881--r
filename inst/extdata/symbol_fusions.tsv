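base	substituent	position	snfg_shape	snfg_color	display_name
GlcN	n-acetyl	2	square	blue	GlcNAc
GalN	n-acetyl	2	square	yellow	GalNAc
ManN	n-acetyl	2	square	green	ManNAc
Neu	n-acetyl	5	diamond	purple	Neu5Ac
Neu	n-glycolyl	5	diamond	light_blue	Neu5Gc
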