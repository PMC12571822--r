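gene_id	EH_LAN	gcHapN_LAN	EH_MV	gcHapN_MV	significance	selection_label
OsDLH1	0.250	46	0.268	28	ns	down
OsDLH2	0.154	18	0.186	11	ns	down
OsDLH3	0.538	98	0.464	38	*	up
OsDLH4	0.501	87	0.464	34	ns	down
OsDLH5	0.041	5	0.062	6	ns	down
OsDLH6	0.424	73	0.364	25	ns	down
OsDLH7	0.318	19	0.343	15	ns	down
OsDLH8	0.203	32	0.155	15	ns	down
OsDLH9	0.316	28	0.438	24	**	up
OsDLH10	0.433	59	0.456	38	ns	down
OsDLH11	0.244	40	0.283	25	ns	down
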