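population	total	known	novel	known_pct	novel_pct	substitution	insertion	deletion	substitution_pct	insertion_pct	deletion_pct	ts_tv
YRI	11176	10441	844	92.4	7.6	9682	671	823	86.6	6.0	7.4	3.67
ESN	7669	7046	653	91.5	8.5	6634	424	611	86.5	5.5	8.0	3.39
PEL	7623	6251	1331	82.5	17.5	6705	418	500	88.0	5.5	6.6	3.41
IBS	7379	6751	667	91.0	9.0	6290	506	583	85.2	6.9	7.9	3.61
PUR	6685	6092	588	91.2	8.8	5849	337	500	87.5	5.0	7.5	3.77
CEU	6477	5781	663	89.8	10.2	5574	417	486	86.1	6.4	7.5	3.80
GIH	6387	5874	559	91.2	8.8	5492	426	470	86.0	6.7	7.4	3.52
CHB	6354	5688	730	88.5	11.5	5312	488	554	83.6	7.7	8.7	3.65
ASW	5760	5286	477	91.7	8.3	5053	296	411	87.7	5.1	7.1	3.60
GWD	5567	5081	480	91.4	8.6	4807	328	432	86.3	5.9	7.8	3.34
MSL	5072	4834	231	95.4	4.6	4531	237	304	89.3	4.7	6.0	3.67
PJL	4561	3999	589	87.1	12.9	3816	317	428	83.7	7.0	9.4	3.50
ITU	4402	3907	490	88.9	11.1	3798	351	253	86.3	8.0	5.7	3.33
ACB	4308	3984	216	95.0	5.0	3806	212	290	88.3	4.9	6.7	3.90
STU	4282	3786	523	87.8	12.2	3607	304	371	84.2	7.1	8.7	3.55
LWK	4245	4047	178	95.8	4.2	3839	153	253	90.4	3.6	6.0	3.94
BEB	3746	3228	404	89.2	10.8	3332	190	224	88.9	5.1	6.0	3.78
TSI	3617	3223	399	89.0	11.0	3104	215	298	85.8	5.9	8.2	3.85
CLM	3016	2728	240	92.0	8.0	2659	160	197	88.2	5.3	6.5	3.58
CHS	2995	2637	369	87.7	12.3	2526	216	253	84.3	7.2	8.4	3.28
CDX	2948	2576	391	86.7	13.3	2515	189	244	85.3	6.4	8.3	3.25
FIN	1803	1646	151	91.6	8.4	1586	81	136	88.0	4.5	7.5	3.94
GBR	1315	1213	117	91.1	8.9	1121	77	117	85.2	5.9	8.9	3.87
JPT	953	879	74	92.2	7.8	814	59	80	85.4	6.2	8.4	3.81
KHV	747	650	95	87.3	12.7	643	45	59	86.1	6.0	7.9	3.37
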