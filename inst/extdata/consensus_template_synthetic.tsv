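position	label	partner_residues
p1	conserved	31,32,33
p2	variable1	34,37
p3	variable2	59
p4	conserved	63,65
p5	other	
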