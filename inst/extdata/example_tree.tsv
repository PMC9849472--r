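mt-MRCA		
M	mt-MRCA	10400T
D4	M	8414T 16362C
M7	M	9824C 16324C
N	mt-MRCA	8701G 9540C
B4	N	16217C
B5	N	8584A 16140C
F1a	N	16162G 16172C
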