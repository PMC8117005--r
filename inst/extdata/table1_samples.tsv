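sample_id	age_years	dnt_percent	vitb12	sfasl	il10	igg	iga	igm	known_chrom	known_pos	known_ref	known_alt	known_cdna
P1	1	5.2	1911	>1000	460	1510	255	131	chr10	90771840	T	C	c.651+2T>C
P2	56	30.7	>2000	>1000	98	975	328	45	chr10	90773878	G	-	NA
P3	47	6.1	>2000	682	66	1410	595	35	chr10	90773947	G	A	NA
P4	56	5.5	>2000	>1000	128	1140	454	94	chr10	90773876	T	A	NA
P5	30	18	1697	>1000	32	901	35	<5	chr10	90773125	G	A	NA
P6	26	12	ND	>1000	62	2385	596	72	chr10	90773100	G	T	NA
P7	23	27	ND	>1000	110	ND	ND	ND	chr10	90773099	G	T	NA
P8	12	4	2098	800	24	1230	300	174	NA	NA	NA	-	c.812_814del
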