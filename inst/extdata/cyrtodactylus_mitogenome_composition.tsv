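# Whole-mitogenome base composition reported for five Cyrtodactylus
# species (DDBJ accessions AP018114-AP018118); heavy-strand orientation.
species	accession	size_bp	cr_size_bp	pctA	pctT	pctG	pctC	gc_content	gc_skew	at_content	at_skew
Cyrtodactylus peguensis	AP018114	16988	1653	29.4	21.5	16.1	33.1	49.2	-0.3455	50.8	0.1552
Cyrtodactylus thirakhupti	AP018115	16795	1454	30.4	21.5	15.3	32.8	48.0	-0.3638	52.0	0.1715
Cyrtodactylus auribalteatus	AP018116	16795	1445	31.1	21.1	15.0	32.9	47.9	-0.3737	52.1	0.1916
Cyrtodactylus chanhomeae	AP018117	17068	1728	31.2	23.3	15.6	29.9	45.5	-0.3143	54.5	0.1450
Cyrtodactylus tigroides	AP018118	16929	1557	30.3	21.5	15.6	32.6	48.2	-0.3527	51.8	0.1699
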