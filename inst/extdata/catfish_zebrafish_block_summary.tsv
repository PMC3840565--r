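linkage_group	total_span_kb	n_blocks	mean_span_kb	max_span_kb	n50_span_kb	n_genes	mean_genes_per_block
LG1	39522	105	361	1997	1276	577	6
LG2	11105	54	206	942	340	202	5
LG3	26165	93	281	1475	519	439	5
LG4	21282	65	327	2091	854	335	6
LG5	36292	80	454	3189	964	503	8
LG6	36722	102	360	2835	810	570	7
LG7	21884	48	456	2341	984	319	8
LG8	26601	92	289	3269	631	434	5
LG9	27314	66	414	3702	932	431	8
LG10	15589	41	380	3247	709	277	9
LG11	26953	72	374	4995	1121	475	8
LG12	22483	79	285	2731	521	389	6
LG13	29613	78	380	2363	707	472	8
LG14	13468	43	313	2631	749	231	6
LG15	27758	78	356	2466	632	453	8
LG16	36037	105	343	1803	684	535	5
LG17	35452	92	385	1651	658	464	6
LG18	19451	68	286	1536	526	333	6
LG19	20872	36	580	3201	1604	269	9
LG20	31788	73	435	3800	844	456	9
LG21	23200	56	414	3730	835	315	6
LG22	28266	69	410	2233	842	431	7
LG23	11486	47	244	977	465	221	5
LG24	24625	46	535	2529	1075	363	10
LG25	23276	79	295	1539	759	407	6
LG26	18055	46	393	3541	803	256	7
LG27	15045	35	430	2465	1103	204	7
LG28	26602	63	422	2382	1010	389	8
LG29	5860	32	183	705	345	126	5
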