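comparison	parameter	estimate	lo90	hi90
sympatric	theta1	2.9127	2.2693	3.6479
sympatric	theta2	2.056	1.5213	2.6660
sympatric	thetaA	0.8661	0.2109	1.5138
sympatric	t	0.9463	0.6388	1.4613
sympatric	m1	0.1375	0.9125	2.0938
sympatric	m2	1.425	0.0125	0.4125
allopatric	theta1	1.4355	1.0803	1.8506
allopatric	theta2	1.4134	1.0549	1.7923
allopatric	thetaA	1.4901	0.6760	2.4426
allopatric	t	0.8863	0.6138	1.3863
allopatric	m1	0.2125	0.0625	0.4375
allopatric	m2	0.0625	0.0125	0.2625
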