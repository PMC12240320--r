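chain	resseq	position
A	5	p1
A	7	p2
A	9	p3
A	12	p4
A	15	p5
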