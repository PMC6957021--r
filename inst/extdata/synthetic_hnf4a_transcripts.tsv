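transcript_id	gene	contig	strand	exons	downstream
SYNTX-175914	HNF4A	chr20sim	+	301-1198,1319-1619,1740-1872	AGAGTGCACTCGTCAGGCCAAGTCTGTTAACGAGAGTACCGA
SYNTX-1030004	HNF4A	chr20sim	+	2215-2814,2935-3522	CGGCTTGCCAAGGAAGTCCCCCCAAGGTTCTGTCGTGTACACAGTAACCCTCACATTATCGTACAGATGTCGGTCTAAGCGGATCCCGCG
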