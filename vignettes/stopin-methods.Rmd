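---
title: "STOP-IN knock-in design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STOP-IN knock-in design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopin)
```

This vignette is the package's own account of the method it implements:
the model of the edit, the parameters that matter, what the synthetic data
generator does and does not emulate, and the choices made where the design
was genuinely open.

## The edit model

The package models a single, idealized editing event. *S. pyogenes* Cas9
binds a 20-nt protospacer followed by an NGG PAM and cuts bluntly 3 bp 5'
of the PAM — between protospacer bases 17 and 18. Homology-directed repair
from a single-stranded oligo then inserts the 43-nt STOP-IN cassette
exactly at the cut, with zero junction errors. Three consequences are
verified, not assumed, on every design:

1. **Putative null.** The edited transcript of each isoform is rebuilt
   from the edited genome and translated. Because the cassette carries a
   stop in every frame, a premature stop must appear within 45 nt of the
   insertion, and because 43 mod 3 = 1, any readthrough product is
   frameshifted. Both are checked per isoform; an isoform whose CDS does
   not contain the insertion is reported as unaffected (isoform-specific
   designs are legitimate, e.g. targeting an exon skipped by one isoform).
2. **No re-cutting.** The insertion splits the protospacer, so the
   original site must vanish from the edited genome (checked by exact
   genome-wide search).
3. **Re-editability.** The cassette's own Cas9 site must appear exactly
   once, in the gene's sense orientation, enabling reversion with a 71-nt
   wild-type oligo.

All coordinates are 0-based half-open on the plus strand throughout the
package; GFF3's 1-based inclusive convention is converted only at the I/O
boundary. This single convention eliminates the off-by-one drift that
plagues mixed-coordinate pipelines; insertion points are "between-bases"
integers under the same convention.

## Strand logic

Two orientations interact and are easy to confuse:

* the **oligo** is synthesized on the chromosome strand that carries the
  PAM (HDR favors the PAM strand when the edit is at the cut site);
* the **cassette** must end up on the gene's *sense* strand in canonical
  orientation, whatever the PAM strand.

So the payload placed in the oligo is the cassette as written when PAM
strand equals sense strand, and its reverse complement otherwise. The
package tests all four gene-strand x PAM-strand combinations and asserts
the sense-strand-cassette guarantee after simulated repair in each.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `arm_len` | 35 | nt | HDR efficiency falls with arm-to-cut distance; 35 nt per side gives the standard 113-nt oligo, short enough for routine synthesis |
| reversion `total_len` | 71 | nt | wild-type oligo spanning the junction; split 35 nt 5' / 36 nt 3' on the sense strand (the split is a package convention — only the total is canonical — and is recorded in the oligo metadata) |
| `max_cds_fraction` | 0.5 | fraction of spliced CDS | operationalizes "early exon": the cut must fall in the first half of the shortest covering isoform's CDS; there is no canonical threshold, so it is exposed and configurable |
| `require_all_isoforms` | TRUE | — | null designs should hit every isoform; disable for deliberate isoform-specific alleles |
| `require_unique` | TRUE | — | exact-match genome-wide uniqueness of protospacer+PAM; a determinism-preserving proxy, **not** an off-target score |
| outer-primer constraints | 18–25 nt, GC 40–60%, Tm 52–62 °C, WT product < 500 bp | — | a <500 bp amplicon makes the +43 bp knock-in shift resolvable on a 2.5% agarose gel; thermodynamic windows are ordinary PCR practice |
| Tm model | SantaLucia 1998 unified NN, 50 mM Na⁺, 250 nM oligo | — | the screen needs a deterministic, defensible estimate, not vendor-exact values |

## Guide ranking and tie-breaking

Candidates are ranked by ascending position of the cut within the
shortest covering spliced CDS (`cds_fraction`), with ties broken by
ascending genomic coordinate and then `+` before `-` strand. The
tie-break carries no biological meaning; it exists so repeated runs and
the CLI emit identical output.

Degenerate inputs are handled conservatively: windows containing N are
skipped (N "matches nothing" in guide scanning); codons containing N
translate to `X`; a gene whose region offers no N20-NGG window returns an
empty, typed result rather than an error.

## The genotyping simulation

PCR is simulated with exact-match binding only, convergent orientation
required, product size measured 5' end of forward to 5' end of reverse
binding site inclusive (the gel-observable amplicon length). NheI
digestion cuts `G^CTAGC`; fragment sizes always sum to the amplicon
length. Genotype calls implement the two-reaction logic: the inner
(universal primer) reaction detects cassette-carrying alleles; the outer
pair sizes the alleles. An animal with the inner product but only the
larger outer band is called a *homozygous candidate* and flagged for
next-generation confirmation, because a deletion allele destroying an
outer primer site would look identical — the simulation deliberately does
not resolve that ambiguity.

Mismatch-tolerant binding, 3'-end stability rules, primer dimers and gel
mobility are all out of scope: the purpose is deterministic band-size
prediction, not PCR physics.

## Screen statistics

Efficiency is `100 * n_KI / n_genotyped`, rounded **half away from zero**
to an integer — the only rounding convention consistent with the packaged
results table (87.5 → 88, 62.5 → 63; base R's `round()` would give 62).
Pooled efficiencies sum counts before dividing, which is what reproduces
the published pooled n of 694; the mean of per-row percentages is a
different (and not used) statistic. The lethal vs non-lethal comparison is
an uncorrected Pearson chi-square on the pooled 2x2 (Yates correction
available by flag; with these counts the conclusion is insensitive to the
choice). The efficiency of lethal targets is reported with the caveat that
it may be an underestimate — F1 animals carrying two loss-of-function
alleles of an essential gene are never recovered — but no correction is
modeled.

## The synthetic fixture generator

`make_fixture()` emulates exactly the features the design logic exercises:
multi-exon, multi-isoform genes on both chromosome strands; stop-free
random coding sequence (ATG-initiated, stop-terminated); guide sites
planted at chosen exons, PAM strands and cut phases; random introns and
intergenic sequence. Rejection sampling regenerates the random sequence
until no isoform carries an internal in-frame stop and every
uniqueness-requested guide occurs exactly once genome-wide, so planted
guides are exact ground truth for oracle tests. Identical seed and spec
give byte-identical FASTA/GFF3/manifest output, and the generator restores
the caller's RNG state.

What it does **not** emulate: real chromosome composition, repeats, codon
usage, UTRs, trans-splicing or operons. Passing tests therefore
demonstrate the correctness of the design arithmetic and strand logic on
clean gene models — not performance on repetitive or poorly annotated
regions of a real genome, where the uniqueness filter and primer design
will simply reject more candidates.

## Problem sizes and verification strategy

The test suite runs on fixtures of a few kilobases (seconds in total):
per-module unit tests, brute-force oracles (per-base spliced-CDS
reconstruction, window-by-window guide enumeration, textbook
Σ(O−E)²/E chi-square agreeing to 1e-10), and property sweeps — a
200-insertion transcript-level null-guarantee sweep in the unit tests and
a 1,000-insertion sweep plus whole-genome spot checks in the acceptance
script, sizes chosen to exercise every phase and strand combination many
times over while keeping the suite fast. The HDR/reversion round trip is
asserted byte-exact for every planted guide.

## Known limitations

* Perfect-HDR assumption: partial repair and NHEJ by-products (in-frame
  insertions, deletions hitting primer sites) are acknowledged in
  genotype calls but not modeled.
* Off-target assessment is exact-match counting only; use a dedicated
  specificity tool for real experiments.
* No NMD prediction or protein-domain annotation: "putative null" is a
  structural label (early premature stop + frameshift in all required
  isoforms), never a phenotypic claim — phenotypic nullness needs
  genetics.
* Stop-codon readthrough is not modeled; the frameshift is reported as
  the independent safeguard.
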