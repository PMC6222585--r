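[{"gene_id":"aex-2-like","protospacer":"ATTACTGCAGCGACATGGGG","pam":"TGG","pam_strand":"+","chrom":"synth_chrX","start":884,"end":907,"cut":901,"cds_offset":291,"phase":0,"exon":3,"unique":true,"isoform_coverage":"aex-2-like.t1","_row":"start"}]
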