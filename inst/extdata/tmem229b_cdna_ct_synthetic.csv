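proxy_snp,sample_id,ct
rs2273596,s01,37.2
rs2273596,s02,38.1
rs2273596,s03,36.8
rs2273596,s04,39.4
rs2273596,s05,37.7
rs2273596,s06,Undetermined
rs2273596,s07,33.5
rs2273596,s08,34.8
rs2273596,s09,35.2
rs2273596,s10,34.1
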