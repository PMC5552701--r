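population	type	size	genome	markers	bins	linkage_groups	length	density
DoumaixShi4185	F2:6	275	A	4538	1243	7	839.70	5.40
DoumaixShi4185	F2:6	275	B	5041	1259	7	770.64	6.54
DoumaixShi4185	F2:6	275	D	1407	338	7	545.73	2.58
Gaocheng8901xZhoumai16	F2:6	176	A	4574	1282	10	1187.30	3.85
Gaocheng8901xZhoumai16	F2:6	176	B	5911	1607	7	1386.09	4.26
Gaocheng8901xZhoumai16	F2:6	176	D	1334	353	14	587.75	2.27
Linmai2xZhong892	F2:6	273	A	3754	1309	12	1252.64	3.00
Linmai2xZhong892	F2:6	273	B	5319	1622	22	1355.18	3.92
Linmai2xZhong892	F2:6	273	D	751	267	11	347.00	2.16
Zhou8425BxChineseSpring	F2:8	245	A	5965	1502	7	847.13	7.04
Zhou8425BxChineseSpring	F2:8	245	B	7699	1606	7	895.75	8.60
Zhou8425BxChineseSpring	F2:8	245	D	1198	352	7	547.18	2.19
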