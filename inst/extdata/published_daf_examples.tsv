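snp	gene	daf_african	daf_nonafrican	published_delta	digits
rs6085324	CHGB	0.1075	0.3187	0.2112	4
rs236150	CHGB	0.2102	0.0019	0.2083	4
rs236152	CHGB	0.6309	0.4176	0.2133	4
rs742710	CHGB	0.2513	0.0506	0.2007	4
rs10770125	IGF2	0.1750	0.4979	0.3229	4
rs3842753	INS	0.2568	0.7581	0.5013	4
rs2291725	GIP	0.14	0.52	0.38	2
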