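# synthetic ChEA-style TF-target edge list (toy example, not real data)
tf	target
TF_B	GENE1
TF_D	GENE2
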