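protein	chrom	pos	rsid	cohorts	cis_trans	cohort_maf	reference_maf	consequence
SUMF2	7	71973324	rs568788425	MANOLIS	cis	0.0080	0.0004	intron
CD1C	1	158292108	rs201448758	MANOLIS+Pomak	cis	0.0121	0.0001	missense
ENO2	12	6862641	rs184861396	MANOLIS+Pomak	cis	0.0045	0.0020	intron
ITGB7	12	53519700	rs541150953	MANOLIS+Pomak	cis	0.0153	0.0018	intron
ACP6	1	121470180	rs114127018	Pomak	cis	0.0090	0.0001	intergenic
APLP1	19	35871901	rs767668877	Pomak	cis	0.0100	0.0000	missense
CD93	1	3888781	rs912070506	Pomak	trans	0.0020	0.0001	intergenic
CD93	2	207672303	rs942471010	Pomak	trans	0.0040	0.0001	intergenic
CD93	2	227266736	rs1396628045	Pomak	trans	0.0040	0.0001	non_transcript_exon
IGFBP7	4	67658568	rs539585543	Pomak	cis	0.0070	0.0002	intron
IL1RL2	2	89009162	rs543843028	Pomak	cis	0.0200	0.0013	intergenic
KYAT1	9	126833282	rs746374838	Pomak	cis	0.0060	0.0000	missense
MMP2	16	55496937	rs144755357	Pomak	cis	0.0130	0.0001	missense
PSGL1	12	97893711	rs185338771	Pomak	cis	0.0040	0.0000	intergenic
VSIG2	11	124706898	rs959226701	Pomak	cis	0.0060	0.0015	intergenic
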