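test_that("FASTA loading normalizes case and validates records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrI", "ACGT", ">chrII desc text", "ggcc"), fa)
  g <- load_genome(fa)
  expect_equal(unname(chrom_lengths(g)), c(4L, 4L))
  expect_named(chrom_lengths(g), c("chrI", "chrII"))
  expect_equal(g$seq[["chrII"]], "GGCC")

  writeLines(c(">a", "ACGU"), fa)
  expect_error(load_genome(fa), "outside A/C/G/T/N")

  writeLines(c(">a", "ACGT", ">a", "GGCC"), fa)
  expect_error(load_genome(fa), "duplicate")

  expect_error(load_genome(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("genomic lookup obeys half-open arithmetic and strand convention", {
  g <- genome_from_sequences(c(chr = "ACGTACGTNN"))
  expect_equal(nchar(genome_seq(g, "chr", 2, 7)), 5L)
  expect_equal(genome_seq(g, "chr", 0, 4), "ACGT")
  expect_equal(genome_seq(g, "chr", 0, 4, "-"),
               reverse_complement("ACGT"))
  # concatenating adjacent half-open slices equals the joint slice
  expect_equal(paste0(genome_seq(g, "chr", 0, 3), genome_seq(g, "chr", 3, 8)),
               genome_seq(g, "chr", 0, 8))
  expect_error(genome_seq(g, "chr", 0, 11), "out of bounds")
  expect_error(genome_seq(g, "nope", 0, 2), "unknown chromosome")
})

test_that("GFF3 coordinates convert 1-based inclusive to 0-based half-open", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">c1", paste(rep("ACGTA", 20), collapse = "")), fa)
  writeLines(c(
    "##gff-version 3",
    "c1\tx\tgene\t11\t19\t.\t+\t.\tID=g1",
    "c1\tx\tmRNA\t11\t19\t.\t+\t.\tID=g1.t1;Parent=g1",
    "c1\tx\tCDS\t11\t19\t.\t+\t0\tID=c;Parent=g1.t1"), gff)
  genome <- load_genome(fa)
  genes <- load_annotation(gff, genome)
  iv <- genes[["g1"]]$isoforms[["g1.t1"]]
  expect_equal(iv$start, 10)
  expect_equal(iv$end, 19)
})

test_that("annotation round trip through GFF3 preserves fixture gene models", {
  fx <- fix_basic()
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fasta(fx$genome, fa)
  write_gff3(fx$genes, gff)
  genome2 <- load_genome(fa)
  genes2 <- load_annotation(gff, genome2)
  expect_identical(genome2$seq, fx$genome$seq)
  for (id in names(fx$genes)) {
    expect_equal(genes2[[id]]$strand, fx$genes[[id]]$strand)
    for (iso in names(fx$genes[[id]]$isoforms)) {
      expect_equal(genes2[[id]]$isoforms[[iso]],
                   fx$genes[[id]]$isoforms[[iso]])
    }
  }
  # minus-strand isoforms come back in transcription order
  gB <- genes2[["gB"]]
  expect_true(all(diff(gB$isoforms[[1]]$start) < 0))
})

test_that("annotation errors: unknown chromosome, missing CDS", {
  fx <- fix_basic()
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrZZ\tx\tgene\t1\t50\t.\t+\t.\tID=g1",
    "chrZZ\tx\tmRNA\t1\t50\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrZZ\tx\tCDS\t1\t50\t.\t+\t0\tID=c;Parent=g1.t1"), gff)
  expect_error(load_annotation(gff, fx$genome), "unknown chromosome")

  writeLines(c(
    "##gff-version 3",
    "chrI\tx\tgene\t1\t50\t.\t+\t.\tID=g1",
    "chrI\tx\tmRNA\t1\t50\t.\t+\t.\tID=g1.t1;Parent=g1"), gff)
  expect_warning(res <- load_annotation(gff, fx$genome), "no CDS")
  expect_length(res, 0)
})

test_that("spliced CDS matches the per-base brute-force oracle exactly", {
  for (fx in list(fix_basic(), fix_multi_iso())) {
    for (id in names(fx$genes)) {
      gene <- fx$genes[[id]]
      for (iso in names(gene$isoforms)) {
        got <- spliced_cds(gene, iso, fx$genome)
        expect_identical(got$seq, brute_spliced_cds(gene, iso, fx$genome))
        # spliced length = sum of interval lengths
        iv <- gene$isoforms[[iso]]
        expect_equal(nchar(got$seq), sum(iv$end - iv$start))
        # coordinate map is bijective: round trip over every CDS base
        expect_equal(anyDuplicated(got$genomic_pos), 0L)
        for (i in c(1L, nchar(got$seq) %/% 2L, nchar(got$seq))) {
          expect_equal(match(got$genomic_pos[i], got$genomic_pos), i)
        }
      }
    }
  }
})

test_that("spliced CDS of a minus-strand single-exon gene is the reverse
          complement of the plus-strand slice", {
  g <- genome_from_sequences(c(c1 = paste0(strrep("T", 10), "ATGAAATAG",
                                           strrep("T", 10))))
  plus <- new_gene_model("gp", chrom = "c1", strand = "+",
                         isoforms = list(t1 = data.frame(start = 10, end = 19)))
  minus <- new_gene_model("gm", chrom = "c1", strand = "-",
                          isoforms = list(t1 = data.frame(start = 10, end = 19)))
  expect_equal(spliced_cds(plus, "t1", g)$seq, "ATGAAATAG")
  expect_equal(spliced_cds(minus, "t1", g)$seq,
               reverse_complement("ATGAAATAG"))
  expect_error(spliced_cds(plus, "t9", g), "unknown isoform")
})

test_that("reverse complement: hand-checked cases, involution, alphabet", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("GCTAGC"), "GCTAGC")
  # hand-computed base by base; must also be a cassette substring
  expect_equal(reverse_complement("GCTTATCACTTAGTCACCTCTGCTC"),
               "GAGCAGAGGTGACTAAGTGATAAGC")
  expect_true(grepl("GAGCAGAGGTGACTAAGTGATAAGC", STOPIN_CASSETTE_SEQ,
                    fixed = TRUE))
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1),
                      replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("ACGU"), "alphabet")
})
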