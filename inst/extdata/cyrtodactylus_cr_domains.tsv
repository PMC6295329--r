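# Control-region domain sizes (bp) and A+T% reported for five
# Cyrtodactylus species (DDBJ accessions AP018114-AP018118).
species	accession	cr_size_bp	cr_at	etas_size_bp	etas_at	ccr_size_bp	ccr_at	csbf_size_bp	csb_size_bp	csb_at	csb1_size_bp	csb2_size_bp	csb3_size_bp
Cyrtodactylus peguensis	AP018114	1653	57.7	496	76.6	312	52.9	20	845	48.4	21	18	18
Cyrtodactylus thirakhupti	AP018115	1454	59.4	495	76.8	311	51.5	20	648	49.9	21	18	18
Cyrtodactylus auribalteatus	AP018116	1445	57.7	566	70.9	246	48.0	20	633	49.8	21	18	18
Cyrtodactylus chanhomeae	AP018117	1728	62.5	647	74.8	254	56.7	20	827	54.7	21	18	18
Cyrtodactylus tigroides	AP018118	1557	57.2	492	73.8	314	54.2	20	751	47.8	21	18	18
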