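species	sample_id	total_reads	label	count
Alopecurus aequalis	M36	2173	Ae1	473
Alopecurus aequalis	M36	2173	Ae2	169
Alopecurus aequalis	M36	2173	Ae3	161
Alopecurus aequalis	M36	2173	Ae4	140
Alopecurus alpinus	L22	10709	Al1	3709
Alopecurus alpinus	L22	10709	Al2	2396
Alopecurus arundinaceus	22	16316	Ar1	2864
Alopecurus arundinaceus	22	16316	Ar2	2504
Alopecurus brachystachyus	M13	7373	Br	3485
Alopecurus x brachystylus	21	26133	Ae1	5828
Alopecurus x brachystylus	21	26133	Ae3	2331
Alopecurus x brachystylus	21	26133	Pr5	2095
Alopecurus x brachystylus	21	26133	B	1722
Alopecurus x brachystylus	21	26133	Pr1	1087
Alopecurus brevifolius	L21	20957	Bf1	7380
Alopecurus brevifolius	L21	20957	Bf2	1879
Alopecurus brevifolius	L21	20957	Bf3	1643
Alopecurus brevifolius	L21	20957	Bf4	1124
Alopecurus geniculatus	L18	5263	Ae1	1809
Alopecurus geniculatus	L18	5263	G	1072
Alopecurus magellanicus	L14	5142	Am1	2051
Alopecurus magellanicus	L14	5142	Am2	447
Alopecurus magellanicus	L14	5142	Am3	235
Alopecurus x marssonii	M11	1880	Ae1	465
Alopecurus x marssonii	M11	1880	Ae2	164
Alopecurus x marssonii	M11	1880	Ae3	158
Alopecurus x marssonii	M11	1880	Ae4	133
Alopecurus myosuroides	20	18721	My1	10044
Alopecurus myosuroides var. breviaristatus	L16	12275	My1	3292
Alopecurus myosuroides var. breviaristatus	L16	12275	My2-2	1971
Alopecurus myosuroides var. breviaristatus	L16	12275	My2-3	1478
Alopecurus ponticus	L20	9229	Po1	2234
Alopecurus ponticus	L20	9229	Po2	1691
Alopecurus ponticus	L20	9229	Po3	1319
Alopecurus ponticus	M8	13553	Po1	3562
Alopecurus ponticus	M8	13553	Po2	3143
Alopecurus ponticus	M8	13553	Po3	1406
Alopecurus ponticus	M8	13553	Po4	1142
Alopecurus pratensis	23	26172	Pr1	5561
Alopecurus pratensis	23	26172	Pr2	2763
Alopecurus pratensis	23	26172	Pr3	1928
Alopecurus pratensis	23	26172	Pr4	1863
Alopecurus pratensis	23	26172	Pr5	1416
Alopecurus pratensis	23	26172	Pr6	1049
Alopecurus pratensis	M5	22148	Pr5	5359
Alopecurus pratensis	M5	22148	Pr1	4775
Alopecurus pratensis	M5	22148	Pr7	3539
Alopecurus pratensis	M6	15362	Pr5	3153
Alopecurus pratensis	M6	15362	Pr1	1732
Alopecurus pratensis	M6	15362	Pr8	1041
Alopecurus pratensis	L30	14946	Pr1	2965
Alopecurus pratensis	L30	14946	Pr2	2863
Alopecurus pratensis	L30	14946	Pr5	1485
Alopecurus pratensis	L30	14946	Pr4	1228
Alopecurus pratensis subsp. alpestris	L15	25290	Pa1	9301
Alopecurus pratensis subsp. alpestris	L15	25290	Pr1	2889
Alopecurus pratensis subsp. alpestris	L15	25290	Pr5	1903
Alopecurus pratensis subsp. alpestris	L15	25290	Pr4	1611
Alopecurus vlassowii	25	21628	Vl1	5248
Alopecurus vlassowii	25	21628	Br	2279
Alopecurus vlassowii	25	21628	Vl2	1006
Limnas stelleri	M17	1704	L1	364
Limnas stelleri	M17	1704	L2	303
Limnas stelleri	M17	1704	L3	195
Limnas stelleri	M17	1704	L4	145
Limnas stelleri	M17	1704	L5	80
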