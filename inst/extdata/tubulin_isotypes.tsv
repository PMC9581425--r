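gene_symbol	family	n_pathogenic	n_gnomad	mcm	phenotype_class	note
TUBA1A	alpha	67	680	5.584	neurodevelopmental	various neuropathies
TUBA1B	alpha	0	696	5.412	cancer_only	chemotherapy resistance roles
TUBA1C	alpha	0	153	2.171	cancer_only	identified as an oncogene
TUBA3D	alpha	0	343	1.533	non_disease	
TUBA3E	alpha	0	531	-0.296	non_disease	single homozygous mutation excluded
TUBA4A	alpha	7	255	3.303	other	neurodegenerative (ALS)
TUBA8	alpha	0	201	0.631	non_disease	recessive splice deletion excluded
TUBB1	beta	6	268	0.003	other	bleeding disorders
TUBB2A	beta	3	192	5.263	neurodevelopmental	gyral simplification, epilepsy
TUBB2B	beta	29	190	5.120	neurodevelopmental	various neuropathies
TUBB3	beta	24	76	4.579	neurodevelopmental	various neuropathies
TUBB4A	beta	38	198	4.262	neurodevelopmental	H-ABC, hypomyelination, dystonia
TUBB4B	beta	2	201	4.498	other	sensorineural degeneration
TUBB5	beta	7	198	5.625	neurodevelopmental	various neuropathies
TUBB6	beta	1	74	2.637	neurodevelopmental	congenital facial palsy
TUBB8	beta	35	464	1.860	other	female infertility
TUBB8B	beta	0	228	-2.372	non_disease	
TUBG1	gamma	8	57	4.155	neurodevelopmental	cortical malformations
TUBG2	gamma	0	113	2.443	non_disease	
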