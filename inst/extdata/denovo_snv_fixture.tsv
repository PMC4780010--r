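chrom	pos	rsid	band	gene	impact	family	frequency
1	2494330	rs2234167	1p36.32	TNFRSF14	NON SYNONYMOUS CODING	NN2624	common
1	41296828	rs34287852	1p34.2	KCNQ4	NON SYNONYMOUS CODING	NN2901	common
2	233537125	rs11550699	2q37.1	EFHD1	NON SYNONYMOUS CODING	NN3752	common
3	193380726	rs200412464	3q29	OPA1	NON SYNONYMOUS CODING	NN3506	very rare
4	169195114	.	4q32.3	DDX60	NON SYNONYMOUS CODING	NN3506	novel
5	825280	rs1809008	5p15.33	ZDHHC11	NON SYNONYMOUS CODING	NN1075	common
7	12409263	rs17165906	7p21.3	VWDE	NON SYNONYMOUS CODING	NN2624	common
7	12409327	rs17165910	7p21.3	VWDE	NON SYNONYMOUS CODING	NN2624	common
7	73969541	rs2301895	7q11.23	GTF2IRD1	NON SYNONYMOUS CODING	1659F	common
9	87338590	.	9q21.33	NTRK2	NON SYNONYMOUS CODING	NN3506	novel
9	101831995	rs10519	9q22.33	COL15A1	NON SYNONYMOUS CODING	1013F	common
9	133577672	.	9q34.12	EXOSC2	NON SYNONYMOUS CODING	NN3506	novel
9	139694569	rs7859194	9q34.3	KIAA1984	NON SYNONYMOUS CODING	1350F	common
13	52544805	rs1801244	13q14.3	ATP7B	NON SYNONYMOUS CODING	NN2624	common
14	20249176	rs2815960	14q11.2	OR4M1	NON SYNONYMOUS CODING	1802F	common
14	24629768	.	14q12	RNF31	NON SYNONYMOUS CODING	1013F	novel
14	25043951	rs61737120	14q12	CTSG	NON SYNONYMOUS CODING	691F	rare
14	102391577	rs3742424	14q32.31	PPP2R5C	NON SYNONYMOUS CODING	1732F	common
15	90818469	rs12595409	15q26.1	NGRN	STOP GAINED	NN3506	common
17	7329310	.	17p13.1	C17orf74	SPLICE SITE ACCEPTOR	1372F	novel
17	11784614	.	17p12	DNAH9	NON SYNONYMOUS CODING	1659F	novel
18	61323012	rs3180227	18q21.33	SERPINB3	NON SYNONYMOUS CODING	894F	common
18	61570529	rs6104	18q21.33	SERPINB2	NON SYNONYMOUS CODING	NN3506	common
19	5691424	.	19p13.3	RPL36	NON SYNONYMOUS CODING	NN3538	novel
19	8191184	rs35025963	19p13.2	FBN3	NON SYNONYMOUS CODING	NN1075	common
19	17660300	rs11666267	19p13.11	FAM129C	NON SYNONYMOUS CODING	1659F	common
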