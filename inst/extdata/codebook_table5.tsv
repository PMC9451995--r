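A1	GTTT
A2	GTTA
A3	TACG
A4	GGAA
A5	TATT
A6	TCCC
B1	GATG
B2	AGTT
B3	ACTG
B4	GCGG
B5	CTAG
B6	GCCG
#	GTAA
Y	TATA
X	CGAG
psi	AGGC
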