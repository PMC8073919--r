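Chr	bp	rsID	EffectAllele	Beta	P	CADD	Gene
1	15539953	rs1316277	T	-3.51	0.00021	15.2	TMEM51
1	165140258	rs7540787	T	-2.70	0.00084	12.7	LMX1A
12	40441521	rs10878035	C	4.85	0.00005	18.9	SLC2A13
13	77062997	rs581121	T	3.17	0.00047	11.4	KCTD12
13	89392881	rs4270027	G	-3.30	0.00039	13.6	SLITRK5
14	86791228	rs1505187	A	3.63	0.00032	10.0	
15	95588003	rs8031253	T	2.98	0.00066	14.1	MCTP2
18	25760028	rs11564299	G	3.44	0.00028	16.5	CDH2
2	201253769	rs3739118	A	2.81	0.00073	20.3	SPATS2L
3	60531242	rs6807877	A	5.36	0.00002	22.8	FHIT
4	126967979	rs6534528	G	-3.77	0.00018	12.1	FAT4
4	12935474	rs6811193	G	-4.23	0.00009	17.4	RAB28
5	32581603	rs6876035	T	2.58	0.00091	10.6	SUB1
6	36772543	rs9296197	G	3.95	0.00014	19.8	CPNE5
8	103190097	rs1265121	T	2.80	0.00079	11.9	NCALD
9	37666010	rs2057643	C	3.50	0.00024	13.2	FRMPD1
2	55555555	rs9000001	A	1.21	0.00200	25.0	DECOYA
5	12345678	rs9000002	C	-0.88	0.00100	14.3	DECOYB
7	23456789	rs9000003	G	2.05	0.04100	11.2	DECOYC
10	34567890	rs9000004	T	-1.50	0.00042	9.99	DECOYD
11	45678901	rs9000005	A	0.73	0.00015	8.20	DECOYE
16	56789012	rs9000006	C	-2.31	0.00063	5.40	DECOYF
17	67890123	rs9000007	G	1.94	0.00037		DECOYG
19	78901234	rs9000008	T	-0.42	0.00088	2.10	DECOYH
20	89012345	rs9000009	A	3.10	0.00700	9.50	DECOYI
22	90123456	rs9000010	C	-1.06	0.50000	1.30	DECOYJ
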