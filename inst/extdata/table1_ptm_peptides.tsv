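group	gene	protein_name	peptide	site	ptm_kind
OC	A1AT	Alpha-1-antitrypsin	KQINDYVEK	1	ACETYL_K
OC	A1AT	Alpha-1-antitrypsin	TDTSHHDQDHPTFNKITPNLAEFAFSLYR	15	ACETYL_K
OC	ALBU	Albumin	EQLKAVMDDFAAFVEK	4	ACETYL_K
OC	ALBU	Albumin	NYAEAKDVFLGMFLYEYAR	6	ACETYL_K
OC	ALBU	Albumin	RHPYFYAPELLFFAK	6	PHOSPHO_Y
OC	ALBU	Albumin	VFDEKPLVEEPQNLIK	5	ACETYL_K
OC	APOA2	Apolipoprotein A-II	EPCVESLVSQYFQTVTDYGK	6	PHOSPHO_S
OC	CO3	Complement C3	KVLLDGVQNPR	1	ACETYL_K
OC	HV307	Ig heavy chain V-III region CAM	DDSKNTLYLQMNSLR	4	ACETYL_K
OC	IGHA1	Ig alpha-1 chain C region	SGNTFRPEVHLLPPPSEELALNELVTLTCLAR	16	PHOSPHO_S
OC	KNG1	Kininogen-1	ETTCSKESNEELTESCETK	2	PHOSPHO_T
OC	TRFE	Serotransferrin	MDAKMYLGYEYVTAIR	4	ACETYL_K
BC	ALBU	Albumin	EQLKAVMDDFAAFVEK	4	ACETYL_K
BC	ALBU	Albumin	KVPQVSTPTLVEVSR	1	ACETYL_K
BC	ALBU	Albumin	NYAEAKDVFLGMFLYEYAR	6	ACETYL_K
BC	APOA1	Apolipoprotein A-I	QLNLKLLDNWDSVTSTFSK	5	ACETYL_K
BC	TRFE	Serotransferrin	KSASDLTWDNLK	1	ACETYL_K
BC	TRFE	Serotransferrin	MDAKMYLGYEYVTAIR	4	ACETYL_K
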