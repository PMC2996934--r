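chrom	non_n_bases	A	B	C	bases_per_snp_A	bases_per_snp_B	bases_per_snp_C
chrA1	164170763	77824	151421	240266	2110	1084	683
chrA2	120172290	59782	118896	180685	2010	1011	665
chrA3	109094838	55010	110129	192266	1983	991	567
chrB1	131184541	62260	118189	196456	2107	1110	668
chrB2	101553943	49898	95152	161014	2035	1067	631
chrB3	96970780	47679	93489	167719	2034	1037	578
chrB4	108425265	53709	104123	170033	2019	1041	638
chrC1	160223031	76483	147928	245762	2095	1083	652
chrC2	107198630	53479	98226	163338	2004	1091	656
chrD1	81705395	45881	88125	130989	1781	927	624
chrD2	67243459	37877	71535	134493	1775	940	500
chrD3	71434721	40297	79074	119894	1773	903	596
chrD4	67338148	34295	65034	88513	1963	1035	761
chrE1	44074055	24513	50193	87236	1798	878	505
chrE2	50431338	27836	56317	94520	1812	895	534
chrE3	36523145	24444	47449	68476	1494	770	533
chrF1	45373584	24292	45507	83877	1868	997	541
chrF2	56475142	29011	55998	93247	1947	1009	606
chrX	83845181	19431	32619	65352	4315	2570	1283
chrUnCf	217904849	101325	198166	323505	2151	1100	674
chrUn	70839159	18959	34246	70797	3736	2069	1001
Total	1992182257	964285	1861816	3078438	2066	1070	647
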