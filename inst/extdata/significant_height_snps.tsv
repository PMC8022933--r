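snp_id	chrom	pos	seg_type	neg_log10_p	r2_percent	qtl_consistent
DSC01H1	Chr01	17015054	abxaa	7.42	1.17	1
DSC01H2	Chr01	21306230	aaxab	6.40	1.70	0
DSC01H3	Chr01	43104197	aaxab	8.52	2.43	1
DSC01H4	Chr01	47744299	aaxab	7.04	1.47	0
DSC03H1	Chr03	2674990	abxaa	7.95	1.02	0
DSC03H2	Chr03	20842084	aaxab	7.37	2.34	0
DSC04H1	Chr04	4423234	aaxab	8.04	1.84	1
DSC04H2	Chr04	20708892	aaxab	8.02	1.59	0
DSC04H3	Chr04	21344054	abxaa	8.07	2.39	0
DSC05H1	Chr05	336929	aaxab	8.18	0.26	1
DSC05H2	Chr05	14685227	aaxab	8.15	1.84	1
DSC05H3	Chr05	14808652	abxaa	7.12	1.99	1
DSC06H1	Chr06	810179	aaxab	6.52	1.35	0
DSC06H2	Chr06	7733888	aaxab	7.10	1.19	0
DSC06H3	Chr06	13575979	abxaa	7.17	1.58	1
DSC06H4	Chr06	16203991	aaxab	8.38	1.13	1
DSC07H1	Chr07	9357528	abxaa	7.00	1.60	0
DSC07H2	Chr07	9920573	aaxab	7.21	2.38	0
DSC07H3	Chr07	10256748	aaxab	6.45	0.64	1
DSC08H1	Chr08	13071948	abxaa	7.87	1.54	0
DSC08H2	Chr08	15844780	abxaa	6.42	1.47	0
DSC08H3	Chr08	17642966	aaxab	7.96	2.05	0
DSC08H4	Chr08	18644603	abxaa	6.40	1.22	0
DSC09H1	Chr09	11900120	abxaa	6.57	1.48	1
DSC10H1	Chr10	4825843	aaxab	9.79	1.96	1
DSC10H2	Chr10	8084409	abxaa	7.53	0.58	1
DSC11H1	Chr11	10094625	aaxab	7.03	0.46	0
DSC11H2	Chr11	16687705	aaxab	7.13	1.97	0
DSC12H1	Chr12	4890486	abxaa	7.07	1.33	0
DSC13H1	Chr13	4732990	abxaa	7.62	1.99	1
DSC13H2	Chr13	10764896	aaxab	6.44	1.72	0
DSC14H1	Chr14	14722576	aaxab	7.27	1.22	1
DSC14H2	Chr14	16676502	aaxab	6.36	1.99	0
DSC15H1	Chr15	6813100	abxaa	7.47	1.37	0
DSC16H1	Chr16	9864836	abxaa	6.45	1.11	1
DSC17H1	Chr17	7378390	abxaa	7.26	1.09	0
DSC17H2	Chr17	10908093	abxaa	8.00	2.01	0
DSC19H1	Chr19	5741825	aaxab	6.66	1.65	0
DSC19H2	Chr19	13202165	abxaa	6.81	0.99	0
DSC19H3	Chr19	13578941	abxaa	8.82	2.64	0
DST45H1	scaffold_45	28115	abxaa	7.06	1.93	0
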