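species	protein	chrom_class	site_type	L	D	P	P_nosingleton	dp_printed	alpha_printed
mel	MOF	A+X	4-fold	3455307	555391	374706	299171	1.856	NA
mel	MOF	A+X	Total	4199054	164454	80282	59102	2.783	0.333
mel	MOF	A	4-fold	2835156	458286	303736	243823	1.880	NA
mel	MOF	A	Non-DC	2251825	23903	1520	1285	18.602	0.899
mel	MOF	X	4-fold	620151	97105	70970	55348	1.754	NA
mel	MOF	X	Non-DC	1263250	77324	43833	32152	2.405	0.270
mel	MOF	X	DC	683979	63227	34929	25665	2.464	0.288
mel	MSL1	A+X	4-fold	3455307	555391	374706	299171	1.856	NA
mel	MSL1	A+X	Total	4139270	240542	91477	72545	3.316	0.440
mel	MSL1	A	4-fold	2835156	458286	303736	243823	1.880	NA
mel	MSL1	A	Non-DC	3325728	187235	66297	53497	3.500	0.463
mel	MSL1	X	4-fold	620151	97105	70970	55348	1.754	NA
mel	MSL1	X	Non-DC	689191	41493	18484	14096	2.944	0.404
mel	MSL1	X	DC	124351	11814	6696	4952	2.386	0.265
mel	MSL2	X	4-fold	620151	97105	70970	55348	1.754	NA
mel	MSL2	X	DC	177823	17469	9191	7329	2.384	0.264
sim	MOF	A+X	4-fold	3396349	580321	161318	115418	5.028	NA
sim	MOF	A+X	Total	123565	13057	5007	3119	4.186	-0.201
sim	MOF	A	4-fold	2812623	483206	138081	101660	4.753	NA
sim	MOF	A	Non-DC	10110	1559	532	430	3.626	-0.311
sim	MOF	X	4-fold	583726	97115	23237	13758	7.059	NA
sim	MOF	X	Non-DC	66219	6675	2740	1623	4.113	-0.716
sim	MOF	X	DC	47236	4823	1735	1066	4.524	-0.560
sim	MSL1	A+X	4-fold	3396349	580321	161318	115418	5.028	NA
sim	MSL1	A+X	Total	1433280	152204	61039	39435	3.860	-0.303
sim	MSL1	A	4-fold	2812623	483206	138081	101660	4.753	NA
sim	MSL1	A	Non-DC	323127	41098	16173	12205	3.367	-0.412
sim	MSL1	X	4-fold	583726	97115	23237	13758	7.059	NA
sim	MSL1	X	Non-DC	975417	99200	40092	24221	4.096	-0.724
sim	MSL1	X	DC	134736	11906	4774	3009	3.957	-0.784
sim	MSL2	X	4-fold	583726	97115	23237	13758	7.059	NA
sim	MSL2	X	DC	22543	2442	751	470	5.196	-0.359
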