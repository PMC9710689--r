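##fileformat=VCFv4.2
##INFO=<ID=CSQ,Number=1,Type=String,Description="Functional consequence">
##FILTER=<ID=q10,Description="Quality below 10">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">
##contig=<ID=chr1>
##contig=<ID=chr2>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TUMOR
chr1	1000	.	A	G	50	PASS	CSQ=missense_variant	GT:AD:DP:AF	0/1:30,10:40:0.25
chr1	2000	.	C	T	50	PASS	CSQ=synonymous_variant	GT:AD:DP	0/1:60,60:120
chr1	3000	.	G	A,T	50	PASS	CSQ=missense_variant	GT:AD:DP:AF	1/2:10,50,40:100:0.5,0.4
chr1	4000	.	CAA	CA	50	PASS	CSQ=frameshift_variant	GT:AD:DP	0/1:70,30:100
chr1	5000	.	T	C	12	q10	CSQ=stop_gained	GT:AD:DP	0/1:5,3:8
chr2	1500	.	G	C	50	PASS	CSQ=missense_variant	GT:AD:DP	0/0:80,0:80
chr2	2500	rs1	A	AGT	50	PASS	CSQ=inframe_insertion	GT:AD:DP	0/1:55,45:100
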