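gene_id	EH_LAN	gcHapN_LAN	EH_MV	gcHapN_MV	significance	selection_label
OsDLH1	0.596	173	0.711	129	**	up
OsDLH2	0.070	19	0.110	16	*	up
OsDLH3	0.642	248	0.658	121	ns	down
OsDLH4	0.530	156	0.595	99	*	up
OsDLH5	0.224	9	0.274	10	ns	down
OsDLH6	0.444	117	0.581	82	**	up
OsDLH7	0.399	53	0.525	45	**	up
OsDLH8	0.347	77	0.488	71	**	up
OsDLH9	0.384	91	0.597	91	**	up
OsDLH10	0.622	236	0.768	155	**	up
OsDLH11	0.589	177	0.730	132	**	up
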