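rsid	chrom	role	neighbor_gene	p_fnk_bmd	p_ra	cfdr_fnk_given_ra	cfdr_ra_given_fnk	ccfdr
rs13413470	2	intron	RFTN2	6.58E-04	5.10E-04	4.39E-02	1.17E-02	4.39E-02
rs7340470	2	NA	RFTN2|MARS2	5.83E-04	9.30E-05	3.57E-02	2.39E-03	3.57E-02
rs700653	2	intron	BOLL	4.75E-04	2.20E-05	4.76E-02	9.31E-04	4.76E-02
rs2880389	2	NA	BOLL|PLCL1	1.92E-04	7.90E-05	3.17E-02	3.22E-03	3.17E-02
rs1318867	2	intron	PLCL1	2.26E-04	1.30E-04	3.20E-02	4.60E-03	3.20E-02
rs11684176	2	intron	PLCL1	1.91E-04	6.90E-04	4.39E-02	2.79E-02	4.39E-02
rs17016749	4	intron	INPP4B	4.74E-05	1.80E-03	1.40E-02	4.19E-02	4.19E-02
rs9378164	6	near-gene-3	LY6G5C	2.96E-04	1.20E-08	3.05E-02	6.06E-07	3.05E-02
rs1266071	6	intron	BAT5	6.35E-03	1.80E-129	3.18E-02	3.93E-127	3.18E-02
rs2734335	6	near-gene-5	C2	5.52E-03	1.90E-122	3.31E-02	4.22E-120	3.31E-02
rs401775	6	intron	SKIV2L	6.06E-03	5.30E-89	3.86E-02	9.63E-87	3.86E-02
rs3115576	6	NA	NOTCH4|C6orf10	6.14E-03	1.50E-141	3.27E-02	3.67E-139	3.27E-02
rs9268055	6	NA	NOTCH4|C6orf10	1.25E-02	1.10E-111	3.67E-02	2.04E-109	3.67E-02
rs2395114	6	NA	NOTCH4|C6orf10	1.29E-05	1.00E-250	2.58E-05	1.87E-249	2.58E-05
rs4713518	6	NA	NOTCH4|C6orf10	7.95E-06	1.00E-250	2.39E-05	5.10E-249	2.39E-05
rs6909427	6	intron	C6orf10	1.10E-02	1.10E-111	3.84E-02	2.27E-109	3.84E-02
rs547261	6	intron	C6orf10	1.11E-03	1.00E-250	1.47E-03	1.01E-248	1.47E-03
rs9368716	6	intron	C6orf10	3.30E-04	1.30E-167	1.98E-03	6.92E-166	1.98E-03
rs1265762	6	intron	C6orf10	2.24E-03	1.10E-117	1.46E-02	1.24E-115	1.46E-02
rs2073046	6	intron	C6orf10	1.07E-05	1.00E-250	2.68E-05	2.75E-249	2.68E-05
rs34043227	6	NA	HLA-DQB2|HLA-DOB	1.47E-02	2.70E-229	4.11E-02	1.74E-226	4.11E-02
rs35571244	6	NA	PPP1R2P1|HLA-DMB	1.14E-02	1.60E-170	4.35E-02	6.76E-168	4.35E-02
rs35599935	6	NA	PPP1R2P1|HLA-DMB	1.09E-02	2.40E-180	4.34E-02	1.18E-177	4.34E-02
rs3101944	6	NA	HLA-DMB|HLA-DMA	1.22E-02	4.60E-137	4.47E-02	1.39E-134	4.47E-02
rs1367727	6	NA	HLA-DMA|BRD2	9.27E-03	1.10E-134	4.50E-02	3.34E-132	4.50E-02
rs10947432	6	intron	C6orf125	5.29E-04	3.00E-06	4.69E-02	1.33E-04	4.69E-02
rs9469623	6	NA	LOC100132252|GRM4	4.67E-04	7.10E-04	4.34E-02	1.78E-02	4.34E-02
rs1109241	11	NA	ETS1|FLI1	4.02E-04	5.20E-05	4.29E-02	2.03E-03	4.29E-02
rs11066320	12	intron	PTPN11	5.32E-04	2.50E-05	4.06E-02	8.34E-04	4.06E-02
rs2099102	19	near-gene-5	EHD2	3.07E-04	1.40E-03	4.30E-02	3.59E-02	4.30E-02
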