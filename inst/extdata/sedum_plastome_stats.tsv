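species	accession_range	length_bp	lsc_bp	ssc_bp	ir_bp	pct_t	pct_c	pct_a	pct_g	at_pct	at_skew	gc_skew
S_alfredii	PV751241-PV751248	149486	81759	16663	25532	31.37	19.23	30.88	18.51	62.25	-0.00787	-0.01908
S_burrito	PV751241-PV751248	150275	82013	16714	25774	31.29	19.30	30.83	18.58	62.12	-0.00741	-0.01901
S_clavatum	PV751241-PV751248	148618	80301	16751	25783	31.25	19.32	30.79	18.63	62.04	-0.00741	-0.01818
S_dasyphyllum	PV751241-PV751248	150714	82779	16657	25639	31.31	19.24	30.87	18.58	62.18	-0.00708	-0.01745
S_furfuraceum	PV751241-PV751248	149554	81201	16745	25804	31.29	19.32	30.79	18.60	62.08	-0.00805	-0.01899
S_hernandezii	PV751241-PV751248	150153	81827	16746	25790	31.33	19.27	30.84	18.57	62.17	-0.00788	-0.01850
S_makinoi	PV751241-PV751248	148925	81173	16680	25536	31.34	19.22	30.89	18.55	62.23	-0.00723	-0.01774
S_palmeri	PV751241-PV751248	149833	81615	16678	25770	31.34	19.28	30.81	18.57	62.15	-0.00853	-0.01876
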