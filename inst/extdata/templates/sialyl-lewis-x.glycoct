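RES
1b:b-dglc-HEX-1:5
2s:n-acetyl
3b:a-lgal-HEX-1:5|6:d
4b:b-dgal-HEX-1:5
5b:a-dgro-dgal-NON-2:6|1:a|2:keto|3:d
6s:n-acetyl
LIN
1:1d(2+1)2n
2:1o(3+1)3d
3:5d(5+1)6n
4:4o(3+2)5d
5:1o(4+1)4d
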