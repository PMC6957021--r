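##fileformat=VCFv4.2
##fileDate=20260930
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##contig=<ID=chr20sim,length=3912>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMPLE
chr20sim	1138	chr20sim:1138_C/T	C	T	100	PASS	.	GT	1/1
chr20sim	1140	chr20sim:1140_G/C	G	C	100	PASS	.	GT	1/1
chr20sim	1486	chr20sim:1486_T/A	T	A	100	PASS	.	GT	1/1
chr20sim	1487	chr20sim:1487_C/G	C	G	100	PASS	.	GT	1/1
chr20sim	1802	chr20sim:1802_C/G	C	G	100	PASS	.	GT	1/1
chr20sim	1803	chr20sim:1803_T/A	T	A	100	PASS	.	GT	1/1
chr20sim	1814	chr20sim:1814_A/G	A	G	100	PASS	.	GT	1/1
chr20sim	1815	chr20sim:1815_G/T	G	T	100	PASS	.	GT	1/1
chr20sim	3521	chr20sim:3521_A/G	A	G	100	PASS	.	GT	1/1
chr20sim	3522	chr20sim:3522_A/G	A	G	100	PASS	.	GT	1/1
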