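lineage	species	i1h	i2h	i3h	i4h	total_is	nb_introns	truncated	flag
Apidae	A_mellifera	2/49	2/85		0/109	243	3	FALSE	
Apidae	B_impatiens	2/101	2/84		0/84	269	3	FALSE	
Megachilidae	M_rotundata	2/101	2/75		0/65	241	3	FALSE	
Formicidae	A_cephalotes	0/92	2/80	2/96	0/84	352	4	FALSE	i1h cell printed with phase 0 where all congeners have phase 2
Formicidae	S_invicta	2/725	2/84	2/130	0/71	1010	4	FALSE	
Formicidae	C_floridanus	2/116	2/77	2/137	0/75	405	4	FALSE	
Formicidae	H_saltator	2/145	2/89	2/97	0/271	457	4	FALSE	printed total 457 inconsistent with listed intron lengths (sum 602)
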