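sample	chrom	pos	ref	alt	depth	alt_fwd	alt_rev	vaf_printed_pct	strand_bias_printed
P1	chr10	90771840	T	C	239	4	6	4.2	0.5318
P2	chr10	90773878	G	-	394	10	20	7.6	0.5125
P3	chr10	90773947	G	A	399	25	21	11.5	0.5497
P4	chr10	90773876	T	A	367	5	5	2.7	0.6237
P5	chr10	90773125	G	A	101	4	4	7.9	0.5148
P6	chr10	90773100	G	T	195	7	10	8.7	0.6249
P7	chr10	90773099	G	T	212	2	2	1.9	0.5279
P1,P4	chr10	90771774	A	G	141	1	2	2.1	0.6497
C5	chr10	90773123	T	C	104	1	2	2.9	0.5451
C18	chr10	90771767	G	A	172	40	56	54.2	0.5219
C32	chr10	90774155	C	T	395	92	98	48.1	0.5337
RV	chr10	90771829	T	C	206	61	51	54.1	0.5133
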