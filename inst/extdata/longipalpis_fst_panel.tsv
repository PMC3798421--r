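locus	fst_symp	sig_symp	Ss_symp	Sf_symp	fst_allo	sig_allo	Ss_allo	Sf_allo
CG9297	0.106	***	26	0	0.486	***	9	0
CG9769	0.059	*	3	0	0.954	***	0	8
eno	0.007	ns	2	0	0.134	***	0	0
kinC	0.145	**	10	0	0.331	***	10	0
mlcc	0.021	ns	3	0	0.250	***	0	0
norpA	0.000	ns	6	0	0.130	***	3	0
obp19a	0.032	*	14	0	0.138	***	8	0
rpL17A	0.115	***	11	0	0.782	***	0	2
rpL36	0.034	ns	29	0	0.300	***	9	0
rpS19	0.351	***	10	0	0.486	***	3	0
sesB	0.334	***	0	0	0.796	***	0	0
slh	0.184	***	13	0	0.568	***	0	0
sec22	0.475	***	3	0	0.461	***	1	1
sod2	0.276	***	7	0	0.337	***	0	0
tfIIAL	0.165	***	15	0	0.350	***	20	0
tropC	0.359	***	5	0	0.705	***	0	1
up	0.547	***	5	0	0.438	***	0	1
zcop	0.036	ns	5	0	0.454	***	0	0
cac	0.076	*	4	0	0.130	***	4	0
para	0.766	***	1	3	0.815	***	0	4
per	0.395	***	6	0	0.471	***	3	0
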