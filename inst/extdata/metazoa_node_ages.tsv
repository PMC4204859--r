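node	age_mya
root	855
metazoa	820
eumetazoa	783
cnidaria	600
nephrozoa	700
deuterostomia	520
protostomia	640
arthropoda	560
insecta	400
cladeI	372
cladeII	300
cladeIII	265
cladeIV	250
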