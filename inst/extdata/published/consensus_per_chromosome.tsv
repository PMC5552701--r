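chromosome	markers	bins	length	density
1A	1496	534	127.38	11.74
1B	2282	470	119.27	19.13
1D	774	170	94.50	8.19
2A	1885	549	152.96	12.32
2B	2872	822	288.30	9.96
2D	728	194	100.64	7.23
3A	1437	476	177.17	8.11
3B	2261	702	149.72	15.10
3D	410	118	102.44	4.00
4A	1547	468	165.54	9.35
4B	865	342	90.15	9.60
4D	118	75	67.71	1.74
5A	1371	537	179.22	7.65
5B	2741	763	198.74	13.79
5D	391	157	118.67	3.29
6A	1953	455	144.96	13.47
6B	2022	623	120.72	16.75
6D	388	136	94.52	4.10
7A	2010	686	194.48	10.34
7B	1835	556	110.32	16.63
7D	306	127	109.45	2.80
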