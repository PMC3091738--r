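cnvr_id	chrom	start	end	length_kb	status	n_animals
1	1	24217581	24340263	122.68	Loss-Gain	13
2	1	45428275	45549702	121.43	Gain	7
3	1	48467320	48606417	139.10	Loss-Gain	24
4	1	65873816	72839149	6965.33	Loss-Gain	50
5	1	84499444	86580142	2080.70	Loss-Gain	101
6	1	102184641	102246547	61.91	Loss-Gain	73
7	1	160653704	161917767	1264.06	Gain	49
8	1	179815713	179914790	99.08	Loss-Gain	197
9	1	181518754	181741363	222.61	Loss-Gain	86
10	1	206491920	206869145	377.23	Loss	12
11	1	222291368	233007189	10715.82	Loss	11
12	1	237242221	237929823	687.60	Gain	8
13	2	11601476	11714214	112.74	Gain	5
14	2	21970642	22174716	204.07	Gain	7
15	2	40533655	41466383	932.73	Loss	270
16	3	56202930	56347970	145.04	Gain	9
17	4	24971805	25077329	105.52	Loss-Gain	39
18	4	33537533	33962195	424.66	Loss-Gain	8
19	4	50569393	51322987	753.59	Gain	14
20	4	119210502	119256548	46.05	Gain	7
21	4	134367793	134519459	151.67	Loss-Gain	21
22	5	23899971	24070933	170.96	Loss-Gain	51
23	5	35733150	37322403	1589.25	Loss-Gain	51
24	5	35933178	36136940	203.76	Gain	12
25	7	77371678	77536074	164.40	Gain	18
26	7	82665585	83053927	388.34	Loss-Gain	18
27	7	97896821	98115996	219.18	Gain	21
28	7	110105319	110156658	51.34	Loss-Gain	11
29	10	4479233	4701713	222.48	Gain	42
30	11	65309203	65381195	71.99	Loss	20
31	11	56381032	57812846	1431.81	Loss-Gain	45
32	13	64352825	64798051	445.23	Loss-Gain	105
33	13	118821556	118923746	102.19	Gain	26
34	14	53301700	55310453	2008.75	Loss-Gain	10
35	14	63834660	63882223	47.56	Loss-Gain	176
36	14	111363926	111540634	176.71	Loss	150
37	14	97526178	99696847	2170.67	Loss-Gain	49
38	15	99843606	100116097	272.49	Loss-Gain	75
39	17	6525429	6635237	109.81	Loss	84
40	8	80936785	81030481	93.70	Loss-Gain	93
41	13	81503361	81601546	98.19	Loss-Gain	118
42	1	130025060	130085466	60.41	Gain	26
43	1	276666775	276786004	119.23	Gain	13
44	5	79779580	79931050	151.47	Gain	34
45	8	35691571	36104826	413.26	Gain	53
46	8	104917016	104968103	51.09	Gain	5
47	11	30072771	30117419	44.65	Loss	38
48	13	94769297	94922644	153.35	Loss	66
49	13	128150975	128360061	209.09	Gain	17
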