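species_id	exon_lengths	intron_lengths
S_frugiperda	119,120,210,100,130,100,132,151,174,150,150,150	3459,344,1645,8467,3290,733,1097,989,494,601,952
B_mori	119,120,210,100,130,100,132,151,174,150,150,150	3280,2841,5599,1203,1197,355,483,1167,1971,1188,795
C_pipiens	911,151,624	62,98
H_sapiens	60,120,269,151,79,232,175,150,450	20000,15000,13118,10000,52295,2125,9110,8711
B_taurus	60,120,269,151,79,232,175,150,450	40000,30000,14139,20000,40145,4795,12223,11832
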