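gene_id	gene	fold_change
MCHK_8175	nifD	228.1625
MCHK_8172	nifE	272.4621
MCHK_8188	nifQ	36.087
MCHK_1835	nifS	11.1585
MCHK_8164	nifT	2.7712
MCHK_8219	fixC	153.2337
MCHK_2178	ntrX	0.9891
MCHK_5476	glnZ	43.3614
MCHK_2333	gltA	6.0617
MCHK_8190	rpoN	28.7755
MCHK_7137	rpoN	40.125
MCHK_5199	rpoH	5.7607
MCHK_2096	rpsN	0.5787
MCHK_1837	sufC	6.589
MCHK_1838	sufD	7.4377
MCHK_1111	sufE	0.5652
MCHK_1839	sufS	9.8869
MCHK_2452	urtB	16.8354
MCHK_2450	urtD	9.3897
MCHK_2449	urtE	5.1336
MCHK_8359	hybC	52.028
MCHK_8347	hypD	5.6356
MCHK_8345	hypE	5.6193
MCHK_5539	acnA	9.0088
MCHK_0267	aldH	0
MCHK_1080	betC	5.9333
MCHK_1499	betI	5.379
MCHK_1081	betI	7.0643
MCHK_5793	cysK	0
MCHK_6087	degPch1	12.494
MCHK_1148	degPch2	22.5974
MCHK_5827	dnaJ	0.6215
MCHK_5828	dnaK	1.7466
MCHK_1003	dsbA	0.6718
MCHK_0964	dxs	5.6548
MCHK_1205	era	6.0056
MCHK_3376	exsG	6.334
MCHK_8419	folD1	8.8978
MCHK_1496	fumC	7.3542
MCHK_2080	fusA	0.9551
MCHK_0391	galE5	0.9348
MCHK_4109	gatB	14.0403
MCHK_7093	glmS	8.8581
MCHK_4716	grpE	1.1287
MCHK_5101	grx	34.8731
MCHK_1705	hemB	1.0837
MCHK_6079	hisB	6.858
MCHK_5153	hisP	5.6978
MCHK_3552	htpG	0.3735
MCHK_3523	kamA	1.2954
MCHK_6499	kdsB	0.8333
MCHK_1589	kdtA	5.6107
MCHK_5594	leuD	5.2354
MCHK_3575	llpU	5.5047
MCHK_2788	maiA	1.0738
MCHK_4398	mdtA	5.1515
MCHK_6536	metK	0.9219
MCHK_5860	metQ	5.4162
MCHK_0867	mexF	58.6485
MCHK_2510	mfd	1.5562
MCHK_4118	mntH	14.1307
MCHK_5902	msrB	10.4404
MCHK_1856	murI	7.7059
MCHK_1985	panB	6.6055
MCHK_1984	panC	6.8577
MCHK_6052	phnN	2.4099
MCHK_6535	phrR	10.2277
MCHK_1763	potA	23.1647
MCHK_0211	potF	0.3783
MCHK_5082	pstB	2.405
MCHK_5085	pstS	6.2484
MCHK_2812	putA	0.2091
MCHK_2418	queA	0
MCHK_6121	rplT	5.046
MCHK_5489	sdhA	5.6783
MCHK_6358	sdhB	1.4018
MCHK_2704	tig	1.6301
MCHK_5374	typA	3.7535
MCHK_3307	ugpC	6.1079
MCHK_0451	uxuA	16.059
MCHK_3900	xfp	0.2442
MCHK_8196	xylB	5.2102
MCHK_8197	xylC	19.882
MCHK_2864	yfbK	13.9193
MCHK_0866	mhl0866	40.6938
MCHK_2865	mhl2865	15.6472
MCHK_4854	mhl4854	7.7335
MCHK_4912	mhl4912	12.7467
MCHK_5957	mhl5957	6.4752
MCHK_8229	mhl8229	8.4814
MCHK_0275	mhr0275	0.4469
MCHK_0381	mhr0381	1.1847
MCHK_0693	mhr0693	10.9707
MCHK_1555	mhr1555	0.8471
MCHK_5071	mhr5071	5.2004
MCHK_5151	mhr5151	7.8098
MCHK_4160	gmhB	1.3228
MCHK_0168	mhl0168	5.9853
MCHK_6013	mhl6013	6.0062
MCHK_0893	mhr0893	1.5161
MCHK_2058	mhl2058	0.4313
MCHK_2321	mhl2321	0.8216
MCHK_5691	mhl5691	8.5342
MCHK_3151	mhl3151	8.1921
MCHK_1970	mhr1970	8.2936
MCHK_3571	mhl3571	12.0058
MCHK_4853	mhl4853	5.2647
MCHK_5785	mhl5785	6.9947
MCHK_6017	mhl6017	5.7227
MCHK_0963	mhr0963	5.4469
MCHK_3741	mhr3741	6.9341
MCHK_5181	mhr5181	7.5806
MCHK_7135	mhr7135	14.553
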