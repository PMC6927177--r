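chr1	toy	exon	101	200	.	+	.	gene_id "gA"; transcript_id "gA.t1";
chr1	toy	exon	301	400	.	+	.	gene_id "gA"; transcript_id "gA.t1";
chr1	toy	exon	1001	1150	.	-	.	gene_id "gB"; transcript_id "gB.t1";
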