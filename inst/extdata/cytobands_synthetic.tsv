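chrom	start	end	band
1	0	10125000	p34
1	10125000	20250000	p33
1	20250000	30375000	p32
1	30375000	40500000	p31
1	40500000	50625000	p24
1	50625000	60750000	p23
1	60750000	70875000	p22
1	70875000	81000000	p21
1	81000000	91125000	p14
1	91125000	101250000	p13
1	101250000	111375000	p12
1	111375000	121500000	p11
1	125000000	133283375	q11
1	133283375	141566750	q12
1	141566750	149850124	q13
1	149850124	158133499	q14
1	158133499	166416874	q15
1	166416874	174700249	q21
1	174700249	182983623	q22
1	182983623	191266998	q23
1	191266998	199550372	q24
1	199550372	207833747	q25
1	207833747	216117122	q31
1	216117122	224400497	q32
1	224400497	232683871	q33
1	232683871	240967246	q34
1	240967246	249250621	q35
2	0	9230000	p25
2	9230000	18460000	p24
2	18460000	27690000	p23
2	27690000	36920000	p22
2	36920000	46150000	p21
2	46150000	55380000	p15
2	55380000	64610000	p14
2	64610000	73840000	p13
2	73840000	83070000	p12
2	83070000	92300000	p11
2	95300000	104543711	q11
2	104543711	113787422	q12
2	113787422	123031132	q13
2	123031132	132274843	q14
2	132274843	141518554	q21
2	141518554	150762264	q22
2	150762264	160005975	q23
2	160005975	169249686	q24
2	169249686	178493397	q31
2	178493397	187737108	q32
2	187737108	196980819	q33
2	196980819	206224530	q34
2	206224530	215468241	q41
2	215468241	224711952	q42
2	224711952	233955662	q43
2	233955662	243199373	q44
3	0	9050000	p25
3	9050000	18100000	p24
3	18100000	27150000	p23
3	27150000	36200000	p22
3	36200000	45250000	p21
3	45250000	54300000	p15
3	54300000	63350000	p14
3	63350000	72400000	p13
3	72400000	81450000	p12
3	81450000	90500000	p11
3	93500000	102210202	q11
3	102210202	110920405	q12
3	110920405	119630608	q13
3	119630608	128340810	q14
3	128340810	137051012	q21
3	137051012	145761215	q22
3	145761215	154471418	q23
3	154471418	163181620	q24
3	163181620	171891822	q31
3	171891822	180602025	q32
3	180602025	189312228	q33
3	189312228	198022430	q34
4	0	8250000	p16
4	8250000	16500000	p15
4	16500000	24750000	p14
4	24750000	33000000	p13
4	33000000	41250000	p12
4	41250000	49500000	p11
4	52700000	61930285	q11
4	61930285	71160570	q12
4	71160570	80390855	q13
4	80390855	89621140	q14
4	89621140	98851425	q15
4	98851425	108081710	q21
4	108081710	117311995	q22
4	117311995	126542281	q23
4	126542281	135772566	q24
4	135772566	145002851	q25
4	145002851	154233136	q31
4	154233136	163463421	q32
4	163463421	172693706	q33
4	172693706	181923991	q34
4	181923991	191154276	q35
5	0	9280000	p15
5	9280000	18560000	p14
5	18560000	27840000	p13
5	27840000	37120000	p12
5	37120000	46400000	p11
5	50700000	59381017	q11
5	59381017	68062035	q12
5	68062035	76743052	q13
5	76743052	85424070	q14
5	85424070	94105087	q15
5	94105087	102786104	q21
5	102786104	111467121	q22
5	111467121	120148139	q23
5	120148139	128829156	q24
5	128829156	137510173	q25
5	137510173	146191190	q31
5	146191190	154872208	q32
5	154872208	163553225	q33
5	163553225	172234243	q34
5	172234243	180915260	q35
6	0	8400000	p17
6	8400000	16800000	p16
6	16800000	25200000	p15
6	25200000	33600000	p14
6	33600000	42000000	p13
6	42000000	50400000	p12
6	50400000	58800000	p11
6	61900000	71001256	q11
6	71001256	80102511	q12
6	80102511	89203766	q13
6	89203766	98305022	q14
6	98305022	107406278	q21
6	107406278	116507534	q22
6	116507534	125608789	q23
6	125608789	134710045	q24
6	134710045	143811300	q31
6	143811300	152912556	q32
6	152912556	162013812	q33
6	162013812	171115067	q34
7	0	9683333	p16
7	9683333	19366667	p15
7	19366667	29050000	p14
7	29050000	38733333	p13
7	38733333	48416667	p12
7	48416667	58100000	p11
7	61100000	70903866	q11
7	70903866	80707733	q12
7	80707733	90511599	q13
7	90511599	100315466	q14
7	100315466	110119332	q15
7	110119332	119923198	q21
7	119923198	129727064	q22
7	129727064	139530931	q23
7	139530931	149334797	q24
7	149334797	159138663	q25
8	0	8620000	p15
8	8620000	17240000	p14
8	17240000	25860000	p13
8	25860000	34480000	p12
8	34480000	43100000	p11
8	48100000	57926402	q11
8	57926402	67752804	q12
8	67752804	77579207	q13
8	77579207	87405609	q14
8	87405609	97232011	q15
8	97232011	107058413	q21
8	107058413	116884815	q22
8	116884815	126711218	q23
8	126711218	136537620	q24
8	136537620	146364022	q25
9	0	9460000	p15
9	9460000	18920000	p14
9	18920000	28380000	p13
9	28380000	37840000	p12
9	37840000	47300000	p11
9	50700000	59751343	q11
9	59751343	68802686	q12
9	68802686	77854030	q13
9	77854030	86905373	q14
9	86905373	95956716	q15
9	95956716	105008059	q21
9	105008059	114059402	q22
9	114059402	123110745	q23
9	123110745	132162088	q24
9	132162088	141213431	q25
10	0	9500000	p14
10	9500000	19000000	p13
10	19000000	28500000	p12
10	28500000	38000000	p11
10	42300000	51623475	q11
10	51623475	60946950	q12
10	60946950	70270424	q13
10	70270424	79593899	q14
10	79593899	88917374	q15
10	88917374	98240849	q21
10	98240849	107564323	q22
10	107564323	116887798	q23
10	116887798	126211272	q24
10	126211272	135534747	q25
11	0	8600000	p16
11	8600000	17200000	p15
11	17200000	25800000	p14
11	25800000	34400000	p13
11	34400000	43000000	p12
11	43000000	51600000	p11
11	55700000	65613314	q11
11	65613314	75526629	q12
11	75526629	85439944	q13
11	85439944	95353258	q14
11	95353258	105266572	q21
11	105266572	115179887	q22
11	115179887	125093202	q23
11	125093202	135006516	q24
12	0	8325000	p14
12	8325000	16650000	p13
12	16650000	24975000	p12
12	24975000	33300000	p11
12	38200000	47765190	q11
12	47765190	57330379	q12
12	57330379	66895569	q13
12	66895569	76460758	q14
12	76460758	86025948	q15
12	86025948	95591137	q21
12	95591137	105156327	q22
12	105156327	114721516	q23
12	114721516	124286706	q24
12	124286706	133851895	q25
13	0	8150000	p12
13	8150000	16300000	p11
13	19500000	29066988	q11
13	29066988	38633976	q12
13	38633976	48200963	q13
13	48200963	57767951	q14
13	57767951	67334939	q15
13	67334939	76901927	q21
13	76901927	86468915	q22
13	86468915	96035902	q23
13	96035902	105602890	q24
13	105602890	115169878	q25
14	0	8050000	p12
14	8050000	16100000	p11
14	19100000	27924954	q11
14	27924954	36749908	q12
14	36749908	45574862	q13
14	45574862	54399816	q14
14	54399816	63224770	q15
14	63224770	72049724	q21
14	72049724	80874678	q22
14	80874678	89699632	q23
14	89699632	98524586	q24
14	98524586	107349540	q25
15	0	7900000	p12
15	7900000	15800000	p11
15	20700000	28883139	q11
15	28883139	37066278	q12
15	37066278	45249418	q13
15	45249418	53432557	q14
15	53432557	61615696	q15
15	61615696	69798835	q21
15	69798835	77981974	q22
15	77981974	86165114	q23
15	86165114	94348253	q24
15	94348253	102531392	q25
16	0	8650000	p14
16	8650000	17300000	p13
16	17300000	25950000	p12
16	25950000	34600000	p11
16	38600000	47225792	q11
16	47225792	55851584	q12
16	55851584	64477376	q13
16	64477376	73103169	q14
16	73103169	81728961	q15
16	81728961	90354753	q16
17	0	11100000	p12
17	11100000	22200000	p11
17	25800000	35032535	q11
17	35032535	44265070	q12
17	44265070	53497605	q13
17	53497605	62730140	q14
17	62730140	71962675	q15
17	71962675	81195210	q16
18	0	7700000	p12
18	7700000	15400000	p11
18	19000000	27439607	q11
18	27439607	35879214	q12
18	35879214	44318821	q13
18	44318821	52758427	q14
18	52758427	61198034	q15
18	61198034	69637641	q16
18	69637641	78077248	q17
19	0	8133333	p13
19	8133333	16266667	p12
19	16266667	24400000	p11
19	28600000	38776328	q11
19	38776328	48952655	q12
19	48952655	59128983	q13
20	0	8533333	p13
20	8533333	17066667	p12
20	17066667	25600000	p11
20	29400000	37806380	q11
20	37806380	46212760	q12
20	46212760	54619140	q13
20	54619140	63025520	q14
21	0	10900000	p11
21	14300000	22757474	q11
21	22757474	31214948	q12
21	31214948	39672421	q13
21	39672421	48129895	q14
22	0	12200000	p11
22	17900000	26251142	q11
22	26251142	34602283	q12
22	34602283	42953424	q13
22	42953424	51304566	q14
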