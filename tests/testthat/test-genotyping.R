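test_that("universal inner primer anatomy", {
  p2 <- universal_inner_primer()
  expect_equal(p2, "GCTTATCACTTAGTCACCTCTGCTC")
  expect_equal(nchar(p2), 25L)
  # reverse complement found at a single offset within the cassette
  rc <- reverse_complement(p2)
  hits <- gregexpr(rc, STOPIN_CASSETTE_SEQ, fixed = TRUE)[[1]]
  expect_equal(length(hits), 1L)
  expect_equal(as.integer(hits), 15L)
})

test_that("nearest-neighbor Tm behaves physically", {
  # GC-richer and longer primers melt higher
  expect_gt(primer_tm("GCGCGCGCGCGCGCGCGCGC"), primer_tm("ATATATATATATATATATAT"))
  expect_gt(primer_tm("ACGTACGTACGTACGTACGTACGT"), primer_tm("ACGTACGTACGTACGT"))
  # a typical 20-mer lands in the usual PCR range
  tm <- primer_tm("AGCTGACCTGAAGGCTCATT")
  expect_gt(tm, 45); expect_lt(tm, 70)
  # higher salt stabilizes the duplex
  expect_gt(primer_tm("AGCTGACCTGAAGGCTCATT", na_mM = 150),
            primer_tm("AGCTGACCTGAAGGCTCATT", na_mM = 50))
  expect_error(primer_tm("ACGN"), "ACGT")
})

test_that("outer primer pair meets constraints and brackets the insertion", {
  fx <- fix_basic()
  pair <- make_edited_pair(fx, 1)
  pp <- pick_outer_primers(fx$genome, "chrI", pair$plan$cut, "+")
  expect_lt(pp$wt_product_size, 500L)
  expect_equal(pp$ki_product_size - pp$wt_product_size, 43L)
  for (p in c(pp$p1, pp$p3)) {
    expect_gte(nchar(p), 18L); expect_lte(nchar(p), 25L)
  }
  expect_true(pp$p1_tm >= 52 && pp$p1_tm <= 62)
  expect_true(pp$p3_tm >= 52 && pp$p3_tm <= 62)
  expect_true(pp$p1_gc >= 40 && pp$p1_gc <= 60)
  # product sizes verified by simulated PCR on pre/post-edit genomes
  wt_prod <- simulate_pcr(pair$wt, pp$p1, pp$p3)
  ki_prod <- simulate_pcr(pair$ki, pp$p1, pp$p3)
  expect_equal(wt_prod$size, pp$wt_product_size)
  expect_equal(ki_prod$size, pp$ki_product_size)
})

test_that("the amplicon shift is 43 bp for every fixture guide", {
  for (fx in list(fix_basic(), fix_multi_iso())) {
    for (i in seq_len(nrow(fx$manifest))) {
      pair <- make_edited_pair(fx, i)
      gene <- pair$gene
      pp <- pick_outer_primers(fx$genome, gene$chrom, pair$plan$cut,
                               gene$strand)
      wt_prod <- simulate_pcr(pair$wt, pp$p1, pp$p3)
      ki_prod <- simulate_pcr(pair$ki, pp$p1, pp$p3)
      expect_equal(nrow(wt_prod), 1L)
      expect_equal(nrow(ki_prod), 1L)
      expect_equal(ki_prod$size - wt_prod$size, 43L)
    }
  }
})

test_that("inner-primer reaction amplifies only cassette-carrying templates", {
  fx <- fix_basic()
  pair <- make_edited_pair(fx, 1)
  pp <- pick_outer_primers(fx$genome, "chrI", pair$plan$cut, "+")
  expect_equal(nrow(simulate_pcr(pair$wt, pp$p1, pp$p2)), 0L)
  inner <- simulate_pcr(pair$ki, pp$p1, pp$p2)
  expect_equal(nrow(inner), 1L)
  expect_equal(inner$size, pp$p2_product_size)
})

test_that("PCR simulation enforces orientation and exact binding", {
  g <- genome_from_sequences(c(t1 = paste0(
    strrep("A", 30), "ACGTGGCTAACGGATTCCA",          # fwd site
    strrep("T", 100), reverse_complement("GGCATTGACCATTGGCCAA"),
    strrep("A", 30))))
  f <- "ACGTGGCTAACGGATTCCA"; r <- "GGCATTGACCATTGGCCAA"
  prod <- simulate_pcr(g, f, r)
  expect_equal(prod$size, 19L + 100L + 19L)
  # swapping the roles still finds the convergent product
  expect_equal(simulate_pcr(g, r, f)$size, prod$size)
  # two same-orientation primers give nothing
  f2 <- "AGGACCTGAACTGGACTCA"
  g2 <- genome_from_sequences(c(t1 = paste0(strrep("A", 30), f,
                                            strrep("T", 50), f2,
                                            strrep("A", 30))))
  expect_equal(nrow(simulate_pcr(g2, f, f2)), 0L)
  # a mismatch abolishes binding
  f_mut <- sub("^A", "T", f)
  expect_equal(nrow(simulate_pcr(g, f_mut, r)), 0L)
  expect_error(simulate_pcr(g, "ACGTACGTACGT", r), "15 nt")
})

test_that("NheI digestion cuts G^CTAGC and conserves length", {
  expect_equal(nhei_digest("GCTAGC"), c(1L, 5L))
  expect_equal(nhei_digest("AAAATTTT"), 8L)
  amp <- paste0(strrep("A", 20), "GCTAGC", strrep("T", 10), "GCTAGC",
                strrep("A", 5))
  frags <- nhei_digest(amp)
  expect_equal(frags, c(21L, 16L, 10L))
  expect_equal(sum(frags), nchar(amp))
  # knock-in amplicon: fragments sum to the KI product size and the
  # cassette's NheI site is actually cut
  fx <- fix_basic()
  pair <- make_edited_pair(fx, 1)
  pp <- pick_outer_primers(fx$genome, "chrI", pair$plan$cut, "+")
  ki_prod <- simulate_pcr(pair$ki, pp$p1, pp$p3)
  amp_ki <- genome_seq(pair$ki, "chrI", ki_prod$start, ki_prod$end, "+")
  frags_ki <- nhei_digest(amp_ki)
  expect_gte(length(frags_ki), 2L)
  expect_equal(sum(frags_ki), pp$ki_product_size)
  # the cassette contributes exactly one new cut relative to wild type
  wt_prod <- simulate_pcr(pair$wt, pp$p1, pp$p3)
  amp_wt <- genome_seq(pair$wt, "chrI", wt_prod$start, wt_prod$end, "+")
  expect_equal(length(frags_ki), length(nhei_digest(amp_wt)) + 1L)
})

test_that("F1 genotype calls reproduce the two-reaction truth table", {
  fx <- fix_basic()
  pair <- make_edited_pair(fx, 1)
  pp <- pick_outer_primers(fx$genome, "chrI", pair$plan$cut, "+")
  band <- function(genomes, fwd, rev) {
    unlist(lapply(genomes, function(g) simulate_pcr(g, fwd, rev)$size))
  }
  genotypes <- list(wildtype = list(pair$wt, pair$wt),
                    het = list(pair$wt, pair$ki),
                    hom = list(pair$ki, pair$ki))
  calls <- lapply(genotypes, function(alleles) {
    outer_bands <- unique(band(alleles, pp$p1, pp$p3))
    inner_bands <- unique(band(alleles, pp$p1, pp$p2))
    classify_f1(outer_bands, inner_bands, pp$wt_product_size,
                pp$ki_product_size)
  })
  expect_equal(calls$wildtype$genotype, "wild-type")
  expect_equal(calls$het$genotype, "heterozygous KI")
  expect_equal(calls$hom$genotype, "homozygous KI candidate")
  expect_true(calls$hom$confirm_next_generation)
  expect_false(calls$het$confirm_next_generation)
  # heterozygote outer pattern is the union of the homozygote patterns
  expect_setequal(unique(band(genotypes$het, pp$p1, pp$p3)),
                  c(unique(band(genotypes$wildtype, pp$p1, pp$p3)),
                    unique(band(genotypes$hom, pp$p1, pp$p3))))
  # inconsistent bands are ambiguous
  expect_equal(classify_f1(c(100), numeric(0), 200, 243)$genotype,
               "ambiguous")
  expect_equal(classify_f1(c(200), c(70), 200, 243)$genotype, "ambiguous")
})

test_that("repetitive flanks produce a design failure naming uniqueness", {
  set.seed(9)
  unit <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                collapse = "")
  g <- genome_from_sequences(c(c1 = paste0(unit, unit)))
  expect_error(pick_outer_primers(g, "c1", 600L, "+"),
               class = "stopin_design_failure")
  err <- tryCatch(pick_outer_primers(g, "c1", 600L, "+"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "uniqueness")
})
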