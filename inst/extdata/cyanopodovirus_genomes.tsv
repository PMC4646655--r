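phage	accession	host_genus	cluster	genome_size_bp	n_orfs	gc_percent
P-RSP2	HQ332139	Prochlorococcus	outlier	42257	48	34.0
P60	AF338467	Synechococcus	MPP-A	46675	55	53.3
Syn5	EF372997	Synechococcus	MPP-A	46214	61	55.0
P-SSP9	HQ316584	Prochlorococcus	MPP-A	46997	54	40.5
S-CBP2	KC310806	Synechococcus	MPP-A	46237	53	55.0
S-CBP42	KC310805	Synechococcus	MPP-A	45218	57	54.6
P-SSP7	AY939843	Prochlorococcus	MPP-B	44970	54	38.8
P-SSP5	GU071100	Prochlorococcus	MPP-B	47055	55	39.2
P-RSP5	GU071102	Prochlorococcus	MPP-B	47741	68	38.7
P-HP1	GU071104	Prochlorococcus	MPP-B	47536	66	39.9
P-SSP2	GU071107	Prochlorococcus	MPP-B	45890	59	37.9
P-GSP1	HQ332140	Prochlorococcus	MPP-B	44945	53	39.6
P-SSP3	HQ332137	Prochlorococcus	MPP-B	46198	56	37.9
P-SSP10	HQ337022	Prochlorococcus	MPP-B	47325	52	39.2
P-SSP11	HQ634152	Prochlorococcus	MPP-B	47039	54	39.2
S-CBP1	KC310802	Synechococcus	MPP-B	46547	51	47.6
S-CBP3	KC310803	Synechococcus	MPP-B	45871	55	47.0
S-CBP4	KC310804	Synechococcus	MPP-B	44147	49	44.4
S-RIP1	HQ317388	Synechococcus	MPP-B	44892	54	42.9
S-RIP2	HQ317389	Synechococcus	MPP-B	45728	56	47.3
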