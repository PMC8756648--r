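id	group	arrow	annotation	printed_length	printed_net_charge	printed_hydrophobicity	tm_helix
LP_23790	secreting	MKKFNFKTMLLLVLASCVFGVVVNVTTSLGPQTTITAQA|SK	transglycosylase	39	3	59	TRUE
LP_08330	secreting	MIKLRQVLKKILIVLMVFVLVFTAFSSSVDTVSA|HR	hypothetical protein	34	4	65	TRUE
LP_04240	secreting	MKKLMCLFGVIGGLVFMSWTSPSIQATA|TN	cell surface protein	28	2	68	TRUE
LP_23670	secreting	MQLLKRIMVIVGTLILGLQVSSVSGLA|AS	cell surface protein	27	2	70	TRUE
LP_28190	secreting	MKRLRHIKLGMLLLSCLAFISMLAITSQA|AA	extracellular protein	29	4	62	TRUE
LP_29340	secreting	MRKWQVAVVMLLAALGSWFAIGTQAQA|KT	glutamine ABC transporter substrate binding, permease	27	2	74	TRUE
LP_23680	secreting	MPNKWWRLILGVMLVLSWAIPVRA|AT	cell surface protein	24	2	79	TRUE
LP_28170	secreting	MKKMMRWLGAILVMISGLSAVVPAQA|AN	cell surface protein	26	3	77	TRUE
LP_23160	secreting	MQKRLRLSLGMLLAVVASLLMMGQVASA|DQ	hypothetical protein	28	3	71	TRUE
LP_24320	secreting	MRFAGKLKKVMIALVAAVTFSTAGLGIAGADLQAQA|AS	D-alanyl-D-alanine carboxypeptidase	36	4	72	TRUE
LP_14210	secreting	MKKIVNWLLGSVLMIAAVTMLSSVSANA|ST	hypothetical protein	28	2	68	TRUE
LP_09710	secreting	MRRLLTGTLVVGGLLLVVCLMAVNGQA|KV	extracellular protein	27	2	74	TRUE
PA_18600	secreting	MVKSRNRILHYILVAVSVVIVVLGFSVIKASA|HG	chitin-binding protein	32	3	66	TRUE
PA_13510	secreting	MYKGFKKYFSNGADRKAGNYPVAKRNKRWLLASAVMLAMFGAGMAQSHAFA|KA	hypothetical protein	51	9	59	TRUE
PA_18250	secreting	MKLKAKLLLVVVPFLMGSVVYHPTPTVQA|KT	DNA-entry nuclease	29	3	69	TRUE
PA_08950	secreting	MNQNWQKPSPKLNWVRFYSIVTILVLVTSVAGLEMLRVSA|HQ	beta-lactamase class A	40	3	58	TRUE
PA_17320	secreting	MKKARWKLLLAGLALLGGISLGQNIISA|NT	hypothetical protein	28	4	71	TRUE
PA_10610	secreting	MKRKWFSLLVAVFLIIGVAIGFGGILHSKSSG|ND	hypothetical protein	32	3	72	TRUE
PA_04150	secreting	MKKAITTASFFLAIFVVFMVGSNAASA|KS	hypothetical protein	27	2	70	TRUE
PA_07000	secreting	METKKRFKMYKSGKKWLVAAIVAGGIATAGSVASVNA|DE	hypothetical protein	38	7	59	TRUE
LP_27290	non_secreting	MRRKLVGYMLSMLTVILALFMLGSTAHA|KE	cell surface protein	28	3	68	TRUE
LP_27220	non_secreting	MKKINKLMILGMLVLGVTGATMINPEMTTA|AH	extracellular protein	30	3	67	TRUE
LP_17340	non_secreting	MKKRFGWFLAIIVALIMTVVPLGQTQHAQA|AD	ABC transporter substrate-binding and permease protein	30	3	70	TRUE
LP_11950	non_secreting	MTKRMSFKFKWVALVATLIVGIGSWQVLAHA|DS	hypothetical protein	31	4	68	TRUE
LP_12630	non_secreting	MLKLIKQRLVWGLVLTATVSGVLSCNVAAHA|TS	D-alanyl-D-alanine carboxypeptidase	31	3	65	TRUE
LP_28330	non_secreting	MKLSKRGLFWLLGLVSFAILLLFSQPLGAQA|AT	cell surface protein	31	3	74	TRUE
LP_27010	non_secreting	MRKLIKACGLMVISMLVGLGIVTSALA|AK	cell surface protein, CscB family	27	3	74	TRUE
PA_14540	non_secreting	MKNNKIIITAAIAGLLGGGVAYGGASFVQNRMEA|TT	serine protease	34	2	68	TRUE
PA_15330	non_secreting	MNYRSILFTTAIATMGAFSFGHSPVSA|HS	hydrolase	27	1	59	FALSE
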