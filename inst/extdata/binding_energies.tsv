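label	dG
WT	-95.59
I845V	-97.91
T622M	-77.20
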