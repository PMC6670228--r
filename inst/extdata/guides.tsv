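name	protospacer	family	region_class	anchor_column	targets_antisense
sgRNA_a87	GATTTTGTGGCTGCAATTG	alpha	post_signal_peptide	87	TRUE
sgRNA_a213	ATGGTTGTTGTGATGGAAA	alpha	epitope_upstream	213	TRUE
sgRNA_a324	GTTGTGGTCGAAATGGTTG	alpha	epitope_downstream	324	TRUE
sgRNA_g86	TTGTTGTGGCCATTGTACT	gamma	post_signal_peptide	86	TRUE
sgRNA_g272	AATGGTTGTTGTGGTTGCTG	gamma	epitope_internal	274	TRUE
sgRNA_g603	TGCTGGGGGAATGATTGTTG	gamma	epitope_downstream	603	TRUE
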