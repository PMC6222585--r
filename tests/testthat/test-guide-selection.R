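test_that("planted guides are recovered at their manifest coordinates", {
  fx <- fix_basic()
  for (i in seq_len(nrow(fx$manifest))) {
    m <- fx$manifest[i, ]
    gene <- fx$genes[[m$gene_id]]
    hits <- find_guides(gene, fx$genome, max_cds_fraction = 1)
    row <- hits[hits$start == m$start & hits$pam_strand == m$pam_strand, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$protospacer, m$protospacer)
    expect_equal(row$pam, m$pam)
    expect_equal(row$cut, m$cut)
    expect_equal(row$end - row$start, 23L)
    expect_equal(row$genome_match_count, 1L)
  }
  # the aex-2 guide specifically
  gA <- find_guides(fx$genes$gA, fx$genome, max_cds_fraction = 1)
  expect_true("ATTACTGCAGCGACATGGGG" %in% gA$protospacer)
})

test_that("cut site sits 3 bp 5' of the PAM on either strand", {
  expect_equal(cut_site(100, 123, "+"), 117)
  expect_equal(cut_site(100, 123, "-"), 106)
  # distance from cut to PAM start measured on the PAM strand is always 3
  fx <- fix_basic()
  for (i in seq_len(nrow(fx$manifest))) {
    m <- fx$manifest[i, ]
    if (m$pam_strand == "+") {
      pam_start <- m$start + 20L          # PAM occupies [start+20, start+23)
      expect_equal(pam_start - m$cut, 3L)
    } else {
      pam_start_on_minus <- m$start + 3L  # PAM 5' end at plus coord start+2
      expect_equal(m$cut - pam_start_on_minus, 3L)
    }
    expect_equal(cut_site(m$start, m$end, m$pam_strand), m$cut)
  }
})

test_that("unfiltered scan equals the brute-force N20-NGG window oracle", {
  for (fx in list(fix_basic(), fix_multi_iso())) {
    for (id in names(fx$genes)) {
      gene <- fx$genes[[id]]
      got <- find_guides(gene, fx$genome, require_all_isoforms = FALSE,
                         max_cds_fraction = 1, require_unique = FALSE)
      got <- got[order(got$start, got$pam_strand), ]
      oracle <- brute_guide_scan(gene, fx$genome)
      expect_equal(nrow(got), nrow(oracle))
      expect_equal(got$start, oracle$start)
      expect_equal(got$pam_strand, oracle$pam_strand)
      expect_equal(got$cut, oracle$cut)
    }
  }
})

test_that("reverse-complementing the chromosome mirrors the guide set", {
  fx <- fix_basic()
  gene <- fx$genes$gA
  clen <- unname(chrom_lengths(fx$genome)[gene$chrom])
  flipped <- genome_from_sequences(stats::setNames(
    reverse_complement(fx$genome$seq[[gene$chrom]]), gene$chrom))
  flip_iv <- function(iv) {
    out <- data.frame(start = clen - iv$end, end = clen - iv$start)
    out[order(out$start, decreasing = TRUE), , drop = FALSE]
  }
  gene_f <- new_gene_model(gene$gene_id, chrom = gene$chrom, strand = "-",
                           isoforms = lapply(gene$isoforms, function(iv) {
                             o <- flip_iv(iv); rownames(o) <- NULL; o
                           }))
  orig <- find_guides(gene, fx$genome, require_all_isoforms = FALSE,
                      max_cds_fraction = 1, require_unique = FALSE)
  mirr <- find_guides(gene_f, flipped, require_all_isoforms = FALSE,
                      max_cds_fraction = 1, require_unique = FALSE)
  expect_equal(nrow(orig), nrow(mirr))
  key <- function(df) {
    k <- paste(df$protospacer, df$pam)
    sort(k)
  }
  expect_equal(key(orig), key(mirr))
  # coordinates mirror: start' = clen - end, strands swap
  m_by_proto <- mirr[match(orig$protospacer, mirr$protospacer), ]
  same <- orig$protospacer %in% mirr$protospacer &
    !duplicated(orig$protospacer)
  expect_equal(m_by_proto$start[same], clen - orig$end[same])
  expect_equal(m_by_proto$pam_strand[same],
               ifelse(orig$pam_strand[same] == "+", "-", "+"))
})

test_that("isoform and early-exon filters restrict candidates as specified", {
  fx <- fix_multi_iso()
  gene <- fx$genes$clik3like
  all_g <- find_guides(gene, fx$genome, require_all_isoforms = FALSE,
                       max_cds_fraction = 1, require_unique = FALSE)
  shared <- find_guides(gene, fx$genome, require_all_isoforms = TRUE,
                        max_cds_fraction = 1, require_unique = FALSE)
  expect_true(nrow(shared) < nrow(all_g))
  expect_true(all(shared$n_isoforms_hit == 2L))
  # every shared guide's cut is inside CDS of every isoform
  for (i in seq_len(nrow(shared))) {
    for (iso in names(gene$isoforms)) {
      iv <- gene$isoforms[[iso]]
      expect_true(any(iv$start < shared$cut[i] & shared$cut[i] < iv$end))
    }
  }
  early <- find_guides(gene, fx$genome, require_all_isoforms = FALSE,
                       max_cds_fraction = 0.5, require_unique = FALSE)
  expect_true(all(early$cds_fraction <= 0.5))
  # ranking: ascending cds_fraction, ties by coordinate then strand
  expect_true(!is.unsorted(early$cds_fraction))
})

test_that("a gene region without NGG windows yields an empty guide set", {
  g <- genome_from_sequences(c(c1 = strrep("AT", 300)))
  gene <- new_gene_model("g0", chrom = "c1", strand = "+",
                         isoforms = list(t1 = data.frame(start = 100,
                                                         end = 400)))
  res <- find_guides(gene, g)
  expect_s3_class(res, "guide_set")
  expect_equal(nrow(res), 0L)
})

test_that("genome-wide match counting equals a sliding-window count", {
  fx <- fix_basic()
  m <- fx$manifest[1, ]
  site <- paste0(m$protospacer, m$pam)
  expect_equal(genome_match_count(site, fx$genome), 1L)
  # plant a second copy (opposite strand) on an extra chromosome
  g2 <- genome_from_sequences(c(fx$genome$seq,
                                extra = paste0(strrep("A", 50),
                                               reverse_complement(site),
                                               strrep("A", 50))))
  expect_equal(genome_match_count(site, g2), 2L)
  # naive oracle over all windows of both strands
  naive <- 0L
  for (chrom_seq in g2$seq) {
    for (s in 0:(nchar(chrom_seq) - 23L)) {
      w <- substr(chrom_seq, s + 1L, s + 23L)
      if (w == site || w == reverse_complement(site)) naive <- naive + 1L
    }
  }
  expect_equal(genome_match_count(site, g2), naive)
  expect_error(genome_match_count("ACGT", fx$genome), "23 nt")
})
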