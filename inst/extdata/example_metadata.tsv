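sample	purity	ploidy	msi
S1	0.85	2.0	MSS
S2	0.69	2.0	MSS
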