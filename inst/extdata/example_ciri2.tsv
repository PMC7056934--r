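circRNA_ID	chr	circRNA_start	circRNA_end	#junction_reads	SM_MS_SMS	#non_junction_reads	junction_reads_ratio	circRNA_type	gene_id	strand
chr1:1001|2000	chr1	1001	2000	12	12_10_2	30	0.44	exon	GENE1	+
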