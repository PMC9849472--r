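s1	Coastal
s2	Coastal
s3	Coastal
s4	Coastal
s5	Coastal
s6	Coastal
s7	Highland
s8	Highland
s9	Highland
s10	Highland
s11	Highland
s12	Highland
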