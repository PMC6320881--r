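name	category	file
n-core	N-core	n-core.glycoct
n-core-fucosylated	N-core	n-core-fucosylated.glycoct
o-core-1	O-core	o-core-1.glycoct
o-core-2	O-core	o-core-2.glycoct
o-core-3	O-core	o-core-3.glycoct
o-core-4	O-core	o-core-4.glycoct
o-core-5	O-core	o-core-5.glycoct
o-core-6	O-core	o-core-6.glycoct
o-core-7	O-core	o-core-7.glycoct
o-core-8	O-core	o-core-8.glycoct
lacnac	epitope	lacnac.glycoct
lewis-a	epitope	lewis-a.glycoct
lewis-x	epitope	lewis-x.glycoct
sialyl-lewis-x	epitope	sialyl-lewis-x.glycoct
blood-group-h	epitope	blood-group-h.glycoct
blood-group-a	epitope	blood-group-a.glycoct
blood-group-b	epitope	blood-group-b.glycoct
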