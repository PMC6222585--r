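# Shared fixtures (built once per test run) and independent brute-force
# oracles. Oracles deliberately avoid the package's optimized code paths:
# they loop base by base / window by window.

# two genes covering both gene strands x both PAM strands, with the aex-2
# guide planted verbatim
fix_basic <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- make_fixture(list(
        fixture_gene("gA", strand = "+", guides = list(
          list(protospacer = "ATTACTGCAGCGACATGGGG", pam_strand = "+",
               exon = 1L, phase = 0L),
          list(pam_strand = "-", exon = 2L, phase = 1L))),
        fixture_gene("gB", strand = "-", guides = list(
          list(pam_strand = "+", exon = 1L, phase = 2L),
          list(pam_strand = "-", exon = 2L, phase = 0L)))
      ), seed = 42L)
    }
    val
  }
})

# clik-3-like: isoform t2 skips exon 2; guides in the isoform-specific exon 2
# and in the shared exon 3
fix_multi_iso <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- make_fixture(list(
        fixture_gene("clik3like", strand = "+",
                     exon_lens = c(90L, 120L, 150L),
                     isoforms = list(clik3like.a = 1:3,
                                     clik3like.c = c(1L, 3L)),
                     guides = list(
                       list(pam_strand = "+", exon = 2L),
                       list(pam_strand = "+", exon = 3L)))
      ), seed = 7L)
    }
    val
  }
})

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# per-base spliced-CDS oracle
brute_spliced_cds <- function(gene, isoform_id, genome) {
  chrom_seq <- genome$seq[[gene$chrom]]
  iv <- gene$isoforms[[isoform_id]]
  out <- character(0)
  for (k in seq_len(nrow(iv))) {
    bases <- vapply(seq(iv$start[k] + 1L, iv$end[k]), function(p)
      substr(chrom_seq, p, p), character(1))
    if (gene$strand == "-") {
      bases <- rev(unname(COMPLEMENT[bases]))
    }
    out <- c(out, bases)
  }
  paste(out, collapse = "")
}

# window-by-window N20-NGG scan keeping cuts strictly inside any CDS interval
# of any isoform; returns start/pam_strand/cut sorted by (start, strand)
brute_guide_scan <- function(gene, genome) {
  chrom_seq <- genome$seq[[gene$chrom]]
  iv <- unique(do.call(rbind, gene$isoforms))
  inside_cds <- function(c) any(iv$start < c & c < iv$end)
  res <- list()
  for (s in 0:(nchar(chrom_seq) - 23L)) {
    w <- substr(chrom_seq, s + 1L, s + 23L)
    if (grepl("^[ACGT]{21}GG$", w) && inside_cds(s + 17L)) {
      res[[length(res) + 1L]] <- data.frame(start = s, pam_strand = "+",
                                            cut = s + 17L)
    }
    if (grepl("^CC[ACGT]{21}$", w) && inside_cds(s + 6L)) {
      res[[length(res) + 1L]] <- data.frame(start = s, pam_strand = "-",
                                            cut = s + 6L)
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), pam_strand = character(0),
                      cut = integer(0)))
  }
  df <- do.call(rbind, res)
  df <- df[order(df$start, df$pam_strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# textbook chi-square statistic
brute_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# random stop-free coding sequence for transcript-level sweeps
random_clean_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  pool <- setdiff(as.vector(outer(outer(bases, bases, paste0), bases,
                                  paste0)),
                  c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(pool, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}
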