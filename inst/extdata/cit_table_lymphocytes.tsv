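cell_type	gene	cpg	lead_snp	coloc_pp4	locus	cit_p	perm_fdr
CD4	ANKRD55	cg21124310	rs6859219	1.00	5q11.2	1.11e-4	7.06e-4
CD4	ANKRD55	cg10404427	rs6859219	1.00	5q11.2	0.0057	0.0044
CD4	ANKRD55	cg23343972	rs6859219	1.00	5q11.2	0.0062	0.0069
CD4	ANKRD55	cg15431103	rs6859219	0.95	5q11.2	0.0496	0.0319
CD4	JAZF1	cg07522171	rs2189966	0.97	7p15.1	3.97e-4	0.0035
CD4	JAZF1	cg11187739	rs4722758	0.99	7p15.1	0.0035	0.0044
CD4	JAZF1	cg16130019	rs917117	0.99	7p15.1	0.0529	0.0319
CD4	ORMDL3	cg18711369	rs12946510	0.86	17q12	4.46e-4	0.0035
CD4	ORMDL3	cg10909506	rs12946510	0.93	17q12	0.0016	0.0044
CD4	FCRL3	cg17134153	rs2210913	0.99	1q23.1	0.0027	0.0044
CD4	FCRL3	cg01045635	rs2210913	0.99	1q23.1	0.0120	0.0296
CD4	IL6ST	cg15431103	rs6859219	0.95	5q11.2	0.0100	0.0296
CD4	IL6ST	cg15667493	rs6859219	0.99	5q11.2	0.0139	0.0296
CD4	IL6ST	cg10404427	rs6859219	1.00	5q11.2	0.0216	0.0305
CD4	IL6ST	cg21124310	rs6859219	1.00	5q11.2	0.0349	0.0305
CD4	IL6ST	cg23343972	rs6859219	1.00	5q11.2	0.0352	0.0305
CD4	C11orf10	cg16213375	rs61897793	1.00	11q12.2	0.0163	0.0296
CD4	TAX1BP1	cg11187739	rs4722758	0.99	7p15.1	0.0470	0.0305
CD4	GSDMB	cg18711369	rs12946510	0.86	17q12	0.0277	0.0305
CD4	GSDMB	cg10909506	rs12946510	0.93	17q12	0.0448	0.0305
B	FCRL3	cg19602479	rs2210913	0.99	1q23.1	4.69e-4	0.0420
B	FCRL3	cg01045635	rs7522061	0.97	1q23.1	5.49e-4	0.0420
B	CCR6	cg15222091	rs3093025	0.98	6q27	0.0101	0.0966
B	CCR6	cg19954286	rs3093025	0.98	6q27	0.0258	0.1330
B	CCR6	cg05094429	rs3093025	0.96	6q27	0.0347	0.1330
B	IKZF3	cg18691862	rs9903250	0.44	17q12	0.0249	0.1330
B	ORMDL3	cg12749226	rs11557466	0.97	17q12	0.0249	0.1330
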