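##fileformat=VCFv4.2
##INFO=<ID=AF,Number=A,Type=Float,Description="Alternate allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NA00001
1	1000	.	A	G	.	PASS	AF=0.35	GT:AD:DP:GQ	1/1:3,48:51:60
1	2000	.	C	T	.	PASS	AF=0.50	GT:AD:DP:GQ	0/1:14,16:30:50
2	3000	.	G	A	.	PASS	AF=0.60	GT:AD:DP:GQ	1/1:0,28:28:84
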