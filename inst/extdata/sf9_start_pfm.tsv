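nt	-10	-9	-8	-7	-6	-5	-4	-3	-2	-1	n_sequences
A	43	36	27	35	27	22	39	88	64	57	168
U	26	34	29	27	31	41	11	0	13	6	168
G	14	17	14	7	28	12	7	10	3	11	168
C	17	13	30	31	14	25	43	2	20	26	168
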