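# stopin

Design and in-silico validation of CRISPR/Cas9 knock-in null alleles built
around the universal 43-nt **STOP-IN cassette**.

## The problem

A clean way to knock out a gene in *C. elegans* (and other organisms) is to
insert a short, fixed cassette into an early coding exon by Cas9 cutting and
homology-directed repair (HDR) from a single-stranded DNA oligo. The STOP-IN
cassette,

```
5'-GGGAAGTTTGTCCAGAGCAGAGGTGACTAAGTGATAAGCTAGC-3'   (43 nt)
```

packs four features into 43 nt:

* **stop codons in all three reading frames** — frames 1 and 2 carry two
  stops each, frame 3 one — so translation terminates regardless of the
  insertion phase;
* **a +1 net frameshift** (43 mod 3 = 1), a second, independent null
  guarantee even under stop-codon readthrough;
* **an exogenous Cas9 target site** (first 20 nt + AGG PAM) that permits
  later re-editing, including clean reversion to wild type;
* **an NheI site** (`GCTAGC`) and a built-in binding site for one universal
  inner genotyping primer (`oHP013r`, 5'-GCTTATCACTTAGTCACCTCTGCTC-3'),
  which together make screening by PCR and RFLP straightforward.

The design logic is: find a 20-nt protospacer followed by an NGG PAM in an
early exon shared by all isoforms; Cas9 cuts bluntly 3 bp 5' of the PAM.
The repair oligo is written on the chromosome strand carrying the PAM and
is `arm5 (35 nt) + cassette + arm3 (35 nt)` = 113 nt, arms identical to the
reference immediately flanking the cut, the cassette oriented so the gene's
*sense* strand acquires it verbatim. The insertion splits the protospacer
between bases 17 and 18, so the edited locus cannot be re-cut.

This package implements that whole desk-side workflow: genome/GFF3 gene
models, guide scanning and ranking, strand-correct oligo construction,
simulated HDR, null verification on every isoform, PCR/RFLP genotyping
assay design with band-pattern genotype calls, reversion-oligo design, the
knock-in screen statistics (per-gene and pooled efficiencies,
lethal-vs-non-lethal chi-square), and a deterministic synthetic fixture
generator so all of it is testable offline.

## Worked example

A small synthetic locus mimicking the *aex-2* design ships with the
package (the published *aex-2* guide planted in exon 3 of a six-exon
gene):

```r
library(stopin)
fa  <- system.file("extdata", "synthetic_aex2_locus.fa",  package = "stopin")
gff <- system.file("extdata", "synthetic_aex2_locus.gff3", package = "stopin")
genome <- load_genome(fa)
gene   <- find_gene(load_annotation(gff, genome), "aex-2-like")

guides <- find_guides(gene, genome)          # shared early exons, unique
g      <- as.list(guides[guides$protospacer == "ATTACTGCAGCGACATGGGG", ])
oligo  <- design_knockin_oligo(g, gene, genome)
print(oligo)
#> <repair_oligo> knockin for aex-2-like, 113 nt on strand + (insertion at synth_chrX:901)
#>   5'-CTACCAATCGCCCGGGTCATTACTGCAGCGACATG[GGGAAGTTTGTCCAGAGCAGAGGTGACTAAGTGATAAGCTAGC]GGGTGGGATCGCCTGAGGTTCATGCTAGCCCATAT-3'

report <- verify_knockin(gene, edit_plan(g, oligo, gene, genome), genome)
print(report)
#> <verification_report>
#>         isoform affected insertion_cds_offset insertion_fraction phase
#> 1 aex-2-like.t1     TRUE                  291              0.422     0
#>   first_stop_offset truncation_fraction frameshift
#> 1               318               0.576       TRUE
#> original Cas9 site destroyed:   TRUE
#> exogenous Cas9 site installed: TRUE (count 1)
#> putative null:                  TRUE
```

The 113-nt oligo carries the cassette (in brackets) between two 35-nt
homology arms. Verification rebuilds the edited transcript: the insertion
lands at spliced-CDS offset 291 (phase 0), the first premature stop
appears at offset 318 — inside the cassette — 57.6% of the wild-type
protein is lost, and the frameshift flag confirms the backup guarantee.

Genotyping primers around the insertion:

```r
pick_outer_primers(genome, gene$chrom, g$cut, gene$strand)
#> <primer_pair> synth_chrX:901 (sense +)
#>   P1 (fwd outer): TAAACGTAACCCAGTCTGCCGACA  Tm 60.0C GC 50%
#>   P3 (rev outer): CGCAACTTCGAGAGCGATGCTAAA  Tm 60.0C GC 50%
#>   P2 (universal inner): GCTTATCACTTAGTCACCTCTGCTC
#>   products: WT 362 bp, KI 405 bp (+43), P1+P2 245 bp
```

The outer pair gives a wild-type product under 500 bp and a knock-in
product exactly 43 bp larger (resolvable on a 2.5% gel); the P1+P2
reaction amplifies only cassette-carrying alleles.

Screen accounting on the packaged 22-experiment results table:

```r
tab <- read_screen_table()
pooled_efficiency(tab)
#> $percent [1] 46   $n_total [1] 694   $n_ki [1] 322
compare_groups(tab)         # lethal vs non-lethal targets
#> rates: A 27% (n = 267) vs B 59% (n = 427)
#> X-squared = 65.8827, df = 1, p = 4.79e-16
```

A thin CLI over the same functions lives in `scripts/stopin`
(`show-cassette`, `design`, `revert`, `stats`, `mix`, `fixtures`).

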