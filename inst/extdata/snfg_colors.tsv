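name	hex
white	#FFFFFF
blue	#0072BC
green	#00A651
yellow	#FFD400
light_blue	#8FCCE9
pink	#F69EA1
purple	#A54399
brown	#A17A4D
orange	#F47920
red	#ED1C24
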