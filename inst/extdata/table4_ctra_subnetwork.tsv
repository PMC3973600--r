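gene_id	gene	regulation
MCHK_1078	betA	up
MCHK_5082	pstB	up
MCHK_5476	glnZ	up
MCHK_5691	mhl5691	up
MCHK_3151	mhl3151	up
MCHK_4201	betA	unchanged
MCHK_0414	betA	unchanged
MCHK_0614	mhr0614	unchanged
MCHK_1015	wbnF	unchanged
MCHK_0391	galE5	unchanged
MCHK_1025	wbiB	unchanged
MCHK_1847	recA	unchanged
MCHK_2439	clpP1	unchanged
MCHK_4371	ctrA	unchanged
MCHK_6536	metK	unchanged
MCHK_1820	mhl1820	unchanged
MCHK_5541	mhr5541	unchanged
MCHK_5341	ftsK1	down
MCHK_5471	ftsK1	down
MCHK_4567	mhr4567	down
MCHK_4720	alkJ	down
MCHK_1789	clpP	down
MCHK_1790	clpX	down
MCHK_6106	fadB	down
MCHK_1018	rfbB	down
MCHK_4463	flgK	down
MCHK_4772	phnG	down
MCHK_4842	clpB	down
MCHK_5239	rcdA	down
MCHK_1035	mhr1035	down
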