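(D_discoideum:1,(T_adhaerens:1,((N_vectensis:1,H_magnipapillata:1)cnidaria:1,((H_sapiens:1,S_kowalevskii:1)deuterostomia:1,(C_teleta:1,(D_pulex:1,(P_humanus:1,(S_frugiperda:1,(A_pisum:1,(T_castaneum:1,(D_melanogaster:1,A_mellifera:1)cladeIV:1)cladeIII:1)cladeII:1)cladeI:1)insecta:1)arthropoda:1)protostomia:1)nephrozoa:1)eumetazoa:1)metazoa:1)root;
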