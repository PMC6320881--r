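RES
1b:a-dgal-HEX-1:5
2s:n-acetyl
3b:b-dglc-HEX-1:5
4s:n-acetyl
5b:b-dglc-HEX-1:5
6s:n-acetyl
LIN
1:1d(2+1)2n
2:3d(2+1)4n
3:1o(3+1)3d
4:5d(2+1)6n
5:1o(6+1)5d
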