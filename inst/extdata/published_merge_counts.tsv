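individual	condition	n_a	n_b	n_c	n_merged
HEA-1	HEA	237039	192201	139218	139104
HEA-2	HEA	249773	249003	229388	229058
HEA-3	HEA	128604	112246	103360	103088
PAT-1	HIV	221756	162754	104389	103834
PAT-2	HIV	254188	229615	211915	211223
PAT-3	HIV	77907	68757	68749	67280
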