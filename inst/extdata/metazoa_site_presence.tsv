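lineage	species	i3l	i4l	i4c	i5l	i6l	i7l	i8l	i7c	i9l	i10l	i11l	truncated	flag
Amoebozoa	D_discoideum												FALSE	outgroup
Placozoa	T_adhaerens						X		+	X			FALSE	
Cnidaria	N_vectensis						X		+	X			FALSE	
Cnidaria	H_magnipapillata						X		+	X			FALSE	
Chordata	H_sapiens	X		+	X		X		+	X			FALSE	
Hemichordata	S_kowalevskii	X		+	X		X		+	X			FALSE	
Annelida	C_teleta	X		+			X		+	X			FALSE	
Branchiopoda	D_pulex	X	X		X		X		+				FALSE	
Phtiraptera	P_humanus	X	X		X		X		+				FALSE	
Lepidoptera	S_frugiperda	X	X		X	X	X	X		X	X	X	FALSE	
Hemiptera	A_pisum		X		X		X		+	X			FALSE	
Coleoptera	T_castaneum		X		X		X			X			FALSE	
Diptera	D_melanogaster		X				X						FALSE	
Hymenoptera	A_mellifera												FALSE	
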