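chrom	length	cen_start	cen_end	is_acrocentric
1	249250621	121500000	125000000	FALSE
2	243199373	92300000	95300000	FALSE
3	198022430	90500000	93500000	FALSE
4	191154276	49500000	52700000	FALSE
5	180915260	46400000	50700000	FALSE
6	171115067	58800000	61900000	FALSE
7	159138663	58100000	61100000	FALSE
8	146364022	43100000	48100000	FALSE
9	141213431	47300000	50700000	FALSE
10	135534747	38000000	42300000	FALSE
11	135006516	51600000	55700000	FALSE
12	133851895	33300000	38200000	FALSE
13	115169878	16300000	19500000	TRUE
14	107349540	16100000	19100000	TRUE
15	102531392	15800000	20700000	TRUE
16	90354753	34600000	38600000	FALSE
17	81195210	22200000	25800000	FALSE
18	78077248	15400000	19000000	FALSE
19	59128983	24400000	28600000	FALSE
20	63025520	25600000	29400000	FALSE
21	48129895	10900000	14300000	TRUE
22	51304566	12200000	17900000	TRUE
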