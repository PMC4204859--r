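lineage	species	i1l	i2l	i3l	i4l	i4c	i5l	i6l	i7l	i8l	i7c	i9l	i10l	i11l	total_is	nb_introns	truncated	flag
Mammalia	H_sapiens			X		+	X		X		+	X			130359	8	FALSE	
Aves	G_gallus			X		+	X		X		+	X			36774	8	FALSE	
Aves	M_gallopavo			X		+	X		X		+	X			37003	8	FALSE	
Aves	T_guttata			X		+	X		X		+	X			43603	8	FALSE	
Reptilia	A_carolinensis			X		+	X		X		+	X			67279	8	FALSE	
Amphibia	X_tropicalis			X		+	X		X		+	X			72102	8	FALSE	
Actinopterygii	D_rerio_B			X		+	X		X		+	X			88524	8	FALSE	
Actinopterygii	T_rubipres			X		+	X		X		+	X			23935	8	FALSE	
Actinopterygii	O_latipes			X		+	X		X		+	X			44674	8	FALSE	
Actinopterygii	O_niloticus			X		+	X		X		+	X			45900	8	FALSE	
Echinodermata	S_purpuratus			X		+	X		X		+	X			58902	8	FALSE	
Hemichordata	S_kowalevskii_A			X		+	X		X		+	X			21376	8	FALSE	
Nematoda	T_spiralis							X	X			X			1122	7	FALSE	
Nematoda	C_brenneri										+	X			652	9	FALSE	
Nematoda	L_loa										+				3347	9	FALSE	
Nematoda	B_malayi										+				2417	9	FALSE	
Nematoda	W_bancrofti										+				2954	10	FALSE	
Nematoda	A_suum										+				13589	10	FALSE	
Annelida	C_teleta			X		+			X		+	X			1183	7	FALSE	
Placozoa	T_adhaerens								X		+	X			682	3	TRUE	totals are lower bounds; 5-prime exon missing
Cnidaria	H_magnipapillata								X		+	X			13440	4	FALSE	
Cnidaria	N_vectensis								X		+	X			2492	4	FALSE	
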