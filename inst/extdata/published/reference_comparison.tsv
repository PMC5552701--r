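chromosome	ref_markers	ref_bins	markers	bins	consistent	new	inconsistent	correlation
1A	2072	303	1496	534	1197	223	76	0.98
1B	3471	352	2282	470	1856	294	132	0.96
1D	1024	179	774	170	679	61	34	0.92
2A	2090	258	1885	549	1350	328	207	0.93
2B	3250	387	2872	822	2098	553	221	0.98
2D	1491	241	728	194	552	103	73	0.94
3A	1800	237	1437	476	1104	240	93	0.97
3B	2491	318	2261	702	1612	509	140	0.93
3D	883	187	410	118	250	100	60	0.88
4A	1928	269	1547	468	1258	197	92	0.96
4B	1444	248	865	342	688	138	39	0.97
4D	296	101	118	75	87	22	9	0.91
5A	2454	338	1371	537	1047	289	35	0.97
5B	2964	376	2741	763	2259	364	118	0.98
5D	1004	199	391	157	231	128	32	0.92
6A	2133	265	1953	455	1491	338	124	0.99
6B	2528	278	2022	623	1568	336	118	0.98
6D	571	127	388	136	260	74	54	0.84
7A	2662	304	2010	686	1505	346	159	0.96
7B	2461	334	1835	556	1502	247	86	0.98
7D	1250	263	306	127	142	92	72	0.96
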