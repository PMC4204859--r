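candidate	context	position_note
ATG1	CGCCGCGACA	first in-frame AUG of the ORF
ATG2	UGACUACUUU	second in-frame AUG
ATG3	CUACUUUAUG	third in-frame AUG, annotated start
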