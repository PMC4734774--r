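Tumor_Sample_Barcode	Chromosome	Start_Position	t_alt_count	t_ref_count
S1	1	1000	10	90
S1	2	2000	25	75
S1	3	3000	50	50
S2	1	1500	12	88
S2	2	2500	30	70
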