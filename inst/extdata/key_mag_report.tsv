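mag_id	rho	rho_sig	min_jsd	repseq_id	taxonomy	percent_identity	alignment_length
bin.293	-0.191	ns	0.0505	repseq1	g_Alistipes;s_Alistipes_inops	91.667	48
bin.72	0.402	ns	0.0419	repseq2	f_Atopobiaceae	98.795	83
bin.326	-0.136	ns	0.0493	repseq3	f_Lachnospiraceae	97.872	423
bin.33	0.599	*	0.0454	repseq4	g_Desulfovibrio	99.342	304
bin.53	0.492	*	0.0570	repseq5	g_Desulfovibrio	100	66
bin.50	-0.247	ns	0.0633	repseq6	g_Helicobacter	99.213	127
bin.324	-0.413	ns	0.0462	repseq7	f_Oscillospiraceae;g_uncultured	96.948	426
bin.80	0.870	***	0.0304	repseq8	g_Akkermansia	100	430
bin.271	0.682	**	0.0385	repseq9	g_Muribaculum	100	443
bin.216	-0.506	*	0.0329	repseq10	g_Muribaculum	100	443
bin.111	0.263	ns	0.0436	repseq11	g_Turicibacter	93.438	320
bin.256	-0.489	*	0.0326	repseq12	g_Prevotellaceae_UCG-001;s_uncultured	90.787	445
bin.322	-0.432	ns	0.0473	repseq13	g_Alistipes	97.065	443
bin.120	0.845	***	0.0340	repseq14	g_Muribaculaceae;s_uncultured	99.097	443
bin.46	0.514	*	0.0453	repseq15	g_Blautia;s_uncultured	88.961	154
bin.268	-0.390	ns	0.0437	repseq16	f_Lachnospiraceae	97.872	423
bin.161	0.567	*	0.0529	repseq17	g_Lachnospiraceae_NK4A136_group	99.291	423
bin.117	-0.475	ns	0.0581	NA	NA	NA	NA
bin.302	0.712	**	0.0381	repseq19	g_Allobaculum;s_uncultured	90.667	450
bin.219	0.594	ns	0.0519	repseq20	g_Clostridium_sp;s_uncultured	98.126	427
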