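lineage	species	i1l	i2l	i3l	i4l	i5l	i6l	i7l	i8l	i9l	i10l	i11l	total_is	nb_introns	truncated	flag
Lepidoptera	S_frugiperda	2/3459	2/344	2/1645	0/8467	1/3290	2/733	2/1097	0/989	0/494	0/601	0/952	22071	11	FALSE	
Lepidoptera	B_mori	2/3280	2/2841	2/5599	0/1203	1/1197	2/355	2/483	0/1167	0/1971	0/1188	0/795	20079	11	FALSE	
Lepidoptera	D_plexippus	2/4756	2/312	2/1263	0/2173	1/512	2/299	2/1177	0/1393	0/468	0/590	0/71	13014	11	FALSE	
Lepidoptera	H_melpomene	2/1633	2/712	2/1821	0/7380	1/1111	2/204	2/146	0/795		0/129	0/248	14179	10	FALSE	
Coleoptera	T_castaneum				0/9139	1/52		2/1524		0/8806			21186	5	FALSE	
Hemiptera	A_pisum				0/67	1/91		2/118		0/62			752	7	FALSE	
Phtiraptera	P_humanus			2/342	0/82	1/215		2/295					3507	9	FALSE	
Diptera	D_melanogaster				0/109			2/65					582	3	FALSE	
Diptera	C_pipiens							2/62	0/98				160	2	FALSE	
Diptera	L_longipalpis							2/94	0/438				3290	3	TRUE	totals are lower bounds; 5-prime exon missing
Mesostigmata	M_occidentallis									0/210			1581	8	FALSE	
Trombidiformes	T_urticae												1173	6	FALSE	
Cladocera	D_pulex			2/65	0/60	1/61		2/55					320	5	FALSE	
Siphonostomatoida	L_salmonis												0	0	FALSE	
Geophilomorpha	S_maritima							2/292		0/56			2591	6	FALSE	
Enterogona	C_intestinalis_A			2/836		1/906		2/820		0/447	0/5797		10989	10	FALSE	
Primates	H_sapiens			2/13118		1/52295		2/2125		0/8711			130359	8	FALSE	
Rodentia	R_norvegicus			2/19848		1/36598		2/1403		0/11243			131971	8	FALSE	
Artiodactyla	B_taurus			2/14139		1/40145		2/4795		0/11832			173134	8	FALSE	
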