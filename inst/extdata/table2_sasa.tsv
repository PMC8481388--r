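group	gene	peptide	site	ptm_kind	localization	n_pdb	aa_intact	aa_ptm	env_intact	env_ptm	helices	motives
OC	A1AT	KQINDYVEK	1	ACETYL_K	Helix	35	119.99	167.54	335.14	364.17	4	1
OC	A1AT	TDTSHHDQDHPTFNKITPNLAEFAFSLYR	15	ACETYL_K	Connection	23	109.78	153.36	346.66	377.32		
OC	ALBU	EQLKAVMDDFAAFVEK	4	ACETYL_K	Helix	156	113.03	135.71	441.31	431.30	30	4
OC	ALBU	KVPQVSTPTLVEVSR	1	ACETYL_K	Helix	172	21.53	7.29	320.08	312.11	3	
OC	ALBU	NYAEAKDVFLGMFLYEYAR	6	ACETYL_K	Connection	162	82.02	108.97	294.16	305.17	3	
OC	ALBU	RHPYFYAPELLFFAK	6	PHOSPHO_Y	Helix	163	22.49	31.01	165.83	154.03	3	
OC	ALBU	VFDEFKPLVEEPQNLIK	6	ACETYL_K	Helix	162	131.78	179.83	278.90	316.22	2	
OC	APOA2	EPCVESLVSQYFQTVTDYGK	6	PHOSPHO_S	Helix	56	69.47	101.31	498.39	501.38	4	n/d
OC	CO3	YFKPGMPFDLMVFVTNPDGSPAYR	3	ACETYL_K	Helix	51	13.86	16.87	134.78	110.51		n/d
OC	HV307	DDSKNTLYLQMNSLR	4	ACETYL_K	Connection	2	126.05	177.73	163	349.85	0	0
OC	IGHA1	SGNTFRPEVHLLPPPSEELALNELVTLTCLAR	16	PHOSPHO_S	Helix	34	103.55	168.88	318.55	361.30	3	1
BC	ALBU	NYAEAKDVFLGMFLYEYA	6	ACETYL_K	Helix	162	82.02	108.97	294.16	305.17	30	3
BC	ALBU	EQLKAVMDDFAAFVEK	4	ACETYL_K	Helix	156	113.03	135.71	441.31	431.30	4	
BC	APOA1	QLNLKLLDNWDSVTSTFSK	5	ACETYL_K	Helix	61	36.75	184.78	317.5	348.78	8	n/d
BC	TRFE	KSASDLTWDNLK	1	ACETYL_K	Helix	32	111.32	155.53	322.75	349.13	22	12
BC	TRFE	MDAKMYLGYEYVTAIR	4	ACETYL_K	Connection	72	64.48	104.60	260.24	279.48	22	12
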