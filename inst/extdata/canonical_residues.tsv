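# Canonical bHLH residue table: 19 defined positions, 11 of them core.
# SYNTHETIC/RECONSTRUCTED: derived from this package's canonical domain
# consensus (see canonical_scheme()), not transcribed from any external
# reference table. Positions use the package's canonical coordinates
# (basic 1-13, helix1 14-28, loop 29-40, helix2 41-55).
position	allowed	core
3	RK	FALSE
4	RK	FALSE
5	HK	TRUE
9	E	TRUE
10	RK	FALSE
12	R	TRUE
13	R	TRUE
16	E	FALSE
18	ILV	TRUE
21	L	FALSE
23	L	TRUE
27	RK	FALSE
28	L	TRUE
45	ILV	TRUE
47	YF	FALSE
48	IL	TRUE
51	LIV	FALSE
52	ILV	TRUE
55	L	TRUE
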