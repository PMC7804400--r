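lead_snp	proxy_snp	gene	r2	dprime	annotation	locus_id	is_secondary_signal	in_inversion_region	isoform_restricted	technology	assay_failed	candidate_source
rs14235	rs14235	BCKDK	1	1	synonymous	BCKDK_ZNF646	FALSE	FALSE	FALSE	TaqMan	FALSE	reported
rs14235	rs749671	ZNF646	0.8	0.9	synonymous	BCKDK_ZNF646	FALSE	FALSE	FALSE	TaqMan	FALSE	reported
rs199347	rs199355	GPNMB	0.93	0.98	synonymous	GPNMB	FALSE	FALSE	FALSE	TaqMan	FALSE	reported
rs823118	rs708723	RAB7L1	0.95	0.98	3'UTR	PARK16	FALSE	FALSE	FALSE	TaqMan	FALSE	reported
rs823118	rs951366	NUCKS1	0.72	-0.98	3'UTR	PARK16	FALSE	FALSE	FALSE	KASP	FALSE	reported
rs1474055	rs76179989	STK39	0.94	0.99	5'UTR	STK39	FALSE	FALSE	FALSE	TaqMan	FALSE	reported
rs8118008	rs58241213	LZTS3	0.77	0.89	5'UTR	LZTS3	FALSE	FALSE	FALSE	KASP	FALSE	reported
rs10799596	rs4649383	SIPA1L2	0.64	-0.99	synonymous	SIPA1L2	FALSE	FALSE	FALSE	KASP	FALSE	reported
rs11158026	rs28481699	WDHD1	0.71	0.86	3'UTR	GCH1_WDHD1	FALSE	FALSE	FALSE	TaqMan	FALSE	reported
rs12637471	rs2270968	MCCC1	0.71	-1	missense	MCCC1	FALSE	FALSE	FALSE	TaqMan	FALSE	reported
rs34311866	rs34311866	TMEM175	1	1	missense	TMEM175	FALSE	FALSE	FALSE	TaqMan	FALSE	reported
rs34884217	rs34884217	TMEM175	1	1	missense	TMEM175	TRUE	FALSE	FALSE	TaqMan	FALSE	reported
rs35749011	rs2230288	GBA	0.69	0.83	missense	GBA	FALSE	FALSE	FALSE	KASP	FALSE	reported
rs14235	rs749670	ZNF646	0.85	0.92	synonymous	BCKDK_ZNF646	FALSE	FALSE	FALSE	KASP	TRUE	synthetic
rs17649553	rs1052553	MAPT	0.96	0.99	synonymous	MAPT_17q21	FALSE	TRUE	FALSE	TaqMan	FALSE	synthetic
rs17649553	rs1881747	KANSL1	0.9	0.97	3'UTR	MAPT_17q21	FALSE	TRUE	FALSE	TaqMan	FALSE	synthetic
rs17649553	rs173664	CRHR1	0.85	0.95	3'UTR	MAPT_17q21	FALSE	TRUE	FALSE	KASP	FALSE	synthetic
rs17649553	rs2668626	SPPL2C	0.88	0.96	missense	MAPT_17q21	FALSE	TRUE	FALSE	KASP	FALSE	synthetic
rs17649553	rs199533	NSF	0.82	0.94	synonymous	MAPT_17q21	FALSE	TRUE	FALSE	TaqMan	FALSE	synthetic
rs356182	rs356165	SNCA	0.76	0.9	3'UTR	SNCA	FALSE	FALSE	TRUE	TaqMan	FALSE	reported
rs1555399	rs2273596	TMEM229B	0.8	0.9	synonymous	TMEM229B	FALSE	FALSE	FALSE	TaqMan	FALSE	synthetic
rs11158026	rs11158026	GCH1	1	1	intronic	GCH1_WDHD1	FALSE	FALSE	FALSE	NA	FALSE	reported
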