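locus	length_bp	n_S1S	n_S2S	n_Lap	n_Pan	S_S1S	S_S2S	S_Lap	S_Pan	pi_S1S	pi_S2S	pi_Lap	pi_Pan	theta_S1S	theta_S2S	theta_Lap	theta_Pan
CG9297	474	32	29	18	25	36	37	42	32	0.024	0.019	0.028	0.009	0.019	0.020	0.027	0.019
CG9769	378	24	24	20	14	12	8	1	3	0.005	0.035	0.000	0.002	0.009	0.006	0.001	0.003
eno	245	28	32	29	30	4	9	3	5	0.002	0.003	0.003	0.002	0.004	0.009	0.003	0.005
kinC	664	17	23	24	24	25	28	32	31	0.010	0.009	0.012	0.010	0.011	0.012	0.013	0.013
mlcc	217	30	28	17	24	12	10	7	7	0.005	0.006	0.008	0.007	0.012	0.014	0.010	0.009
norpA	104	32	30	38	25	8	5	9	9	0.020	0.014	0.017	0.024	0.019	0.012	0.021	0.023
obp19a	164	32	31	28	26	16	17	13	13	0.029	0.033	0.026	0.028	0.024	0.026	0.020	0.021
rpL17A	302	31	31	25	14	13	22	7	2	0.013	0.014	0.007	0.003	0.011	0.019	0.006	0.002
rpL36	450	21	16	32	23	44	48	25	26	0.025	0.031	0.020	0.015	0.029	0.034	0.015	0.017
rpS19	300	33	40	27	10	20	27	17	10	0.016	0.019	0.017	0.010	0.017	0.021	0.015	0.012
sesB	89	23	26	21	15	2	1	0	2	0.004	0.006	0.000	0.004	0.006	0.003	0.000	0.007
slh	258	27	30	19	16	22	24	11	12	0.028	0.018	0.011	0.015	0.023	0.024	0.013	0.015
sec22	429	17	15	29	16	26	19	14	24	0.013	0.015	0.007	0.020	0.018	0.014	0.008	0.017
sod2	310	26	27	27	16	10	15	5	3	0.008	0.008	0.006	0.002	0.009	0.013	0.005	0.003
tfIIAL	377	14	18	20	38	23	33	29	28	0.020	0.030	0.020	0.020	0.022	0.029	0.025	0.019
tropC	483	27	27	29	31	12	12	3	10	0.003	0.004	0.000	0.003	0.007	0.007	0.002	0.005
up	404	21	22	14	16	19	11	14	10	0.010	0.006	0.011	0.009	0.013	0.008	0.011	0.008
zcop	386	30	16	28	21	14	10	6	7	0.005	0.007	0.003	0.004	0.010	0.008	0.004	0.005
cac	109	23	22	20	26	12	5	14	6	0.025	0.025	0.066	0.026	0.043	0.018	0.053	0.021
para	377	27	22	21	29	12	8	2	10	0.004	0.004	0.002	0.005	0.009	0.006	0.002	0.007
per	266	24	23	23	19	27	22	20	18	0.024	0.017	0.018	0.014	0.027	0.022	0.020	0.019
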