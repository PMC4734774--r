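##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TUMOR
1	1000	.	A	T	.	PASS	.	GT:AD	0/1:38,12
1	2000	.	C	G	.	PASS	.	GT:AD	0/1:60,20
2	3000	.	G	A	.	PASS	.	GT:AD	0/1:45,15
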