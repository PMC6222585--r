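##gff-version 3
synth_chrX	stopin	gene	501	1465	.	+	.	ID=aex-2-like;Name=aex-2-like
synth_chrX	stopin	mRNA	501	1465	.	+	.	ID=aex-2-like.t1;Parent=aex-2-like
synth_chrX	stopin	exon	501	590	.	+	.	ID=aex-2-like.t1:exon1;Parent=aex-2-like.t1
synth_chrX	stopin	CDS	501	590	.	+	0	ID=aex-2-like.t1:CDS1;Parent=aex-2-like.t1
synth_chrX	stopin	exon	646	765	.	+	.	ID=aex-2-like.t1:exon2;Parent=aex-2-like.t1
synth_chrX	stopin	CDS	646	765	.	+	0	ID=aex-2-like.t1:CDS2;Parent=aex-2-like.t1
synth_chrX	stopin	exon	821	970	.	+	.	ID=aex-2-like.t1:exon3;Parent=aex-2-like.t1
synth_chrX	stopin	CDS	821	970	.	+	0	ID=aex-2-like.t1:CDS3;Parent=aex-2-like.t1
synth_chrX	stopin	exon	1026	1145	.	+	.	ID=aex-2-like.t1:exon4;Parent=aex-2-like.t1
synth_chrX	stopin	CDS	1026	1145	.	+	0	ID=aex-2-like.t1:CDS4;Parent=aex-2-like.t1
synth_chrX	stopin	exon	1201	1320	.	+	.	ID=aex-2-like.t1:exon5;Parent=aex-2-like.t1
synth_chrX	stopin	CDS	1201	1320	.	+	0	ID=aex-2-like.t1:CDS5;Parent=aex-2-like.t1
synth_chrX	stopin	exon	1376	1465	.	+	.	ID=aex-2-like.t1:exon6;Parent=aex-2-like.t1
synth_chrX	stopin	CDS	1376	1465	.	+	0	ID=aex-2-like.t1:CDS6;Parent=aex-2-like.t1
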