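#!/usr/bin/env Rscript
# Thin command-line front-end over the stopin package.
#
#   stopin show-cassette
#   stopin design   --fasta g.fa --gff a.gff3 --gene ID [--max-cds-fraction F]
#                   [--any-isoform] [--top N] [--arm-len L] [--json]
#   stopin revert   --fasta edited.fa --chrom C --strand {+,-}
#   stopin stats    [--table results.tsv] [--json]
#   stopin mix      [--marker dpy-10|unc-58]
#   stopin fixtures --out DIR [--seed S]

suppressPackageStartupMessages(library(stopin))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) {
  cat("usage: stopin <show-cassette|design|revert|stats|mix|fixtures> [options]\n")
  quit(status = 1)
}
cmd <- argv[1]
opts <- argv[-1]
val <- function(flag, default = NULL) {
  i <- match(flag, opts)
  if (is.na(i) || i == length(opts)) default else opts[i + 1L]
}
has <- function(flag) flag %in% opts

if (cmd == "show-cassette") {
  print(stopin_cassette())
  print(frame_report(STOPIN_CASSETTE_SEQ))
} else if (cmd == "design") {
  genome <- load_genome(val("--fasta"))
  genes <- load_annotation(val("--gff"), genome)
  gene <- find_gene(genes, val("--gene"))
  guides <- find_guides(gene, genome,
                        require_all_isoforms = !has("--any-isoform"),
                        max_cds_fraction =
                          as.numeric(val("--max-cds-fraction", "0.5")))
  top <- min(nrow(guides), as.integer(val("--top", "5")))
  if (top == 0L) {
    cat("no candidate guides pass the filters\n"); quit(status = 1)
  }
  arm <- as.integer(val("--arm-len", "35"))
  rows <- lapply(seq_len(top), function(i) {
    g <- as.list(guides[i, ])
    oligo <- design_knockin_oligo(g, gene, genome, arm_len = arm)
    plan <- edit_plan(g, oligo, gene, genome)
    pp <- tryCatch(pick_outer_primers(genome, gene$chrom, g$cut,
                                      gene$strand),
                   error = function(e) NULL)
    data.frame(rank = i, crRNA = g$protospacer, pam = g$pam,
               pam_strand = g$pam_strand, cut = g$cut,
               cds_fraction = round(g$cds_fraction, 3),
               repair_oligo = oligo$full_sequence,
               p1 = if (is.null(pp)) NA else pp$p1,
               p3 = if (is.null(pp)) NA else pp$p3,
               wt_bp = if (is.null(pp)) NA else pp$wt_product_size,
               ki_bp = if (is.null(pp)) NA else pp$ki_product_size,
               edited_local = plan$expected_local_sense,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (has("--json")) {
    cat(jsonlite::toJSON(out, pretty = TRUE, auto_unbox = TRUE), "\n")
  } else {
    write.table(out, stdout(), sep = "\t", quote = FALSE, row.names = FALSE)
  }
} else if (cmd == "revert") {
  genome <- load_genome(val("--fasta"))
  oligo <- design_reversion_oligo(genome, val("--chrom"),
                                  val("--strand", "+"))
  cat("crRNA (exogenous site):", attr(oligo, "crRNA"), "\n")
  cat("reversion oligo (", nchar(oligo$full_sequence), " nt): ",
      oligo$full_sequence, "\n", sep = "")
} else if (cmd == "stats") {
  tab_path <- val("--table")
  tab <- if (is.null(tab_path)) read_screen_table() else
    read_screen_table(tab_path)
  tab$percent_ki <- ki_percent(tab$n_genotyped, tab$n_ki)
  pooled <- pooled_efficiency(tab)
  cmp <- tryCatch(compare_groups(tab), error = function(e) NULL)
  if (has("--json")) {
    cat(jsonlite::toJSON(list(table = tab, pooled = pooled,
                              lethal_vs_nonlethal = if (!is.null(cmp))
                                list(statistic = cmp$statistic,
                                     p_value = cmp$p_value,
                                     rates = cmp$rates)),
                         pretty = TRUE, auto_unbox = TRUE), "\n")
  } else {
    write.table(tab, stdout(), sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("\npooled: %d%% (%d/%d)\n", pooled$percent, pooled$n_ki,
                pooled$n_total))
    if (!is.null(cmp)) print(cmp)
  }
} else if (cmd == "mix") {
  print(injection_mix(val("--marker", "dpy-10")))
} else if (cmd == "fixtures") {
  fx <- make_fixture(list(
    fixture_gene("demoA", strand = "+", guides = list(
      list(pam_strand = "+", exon = 1L), list(pam_strand = "-", exon = 2L))),
    fixture_gene("demoB", strand = "-", guides = list(
      list(pam_strand = "+", exon = 2L)))),
    seed = as.integer(val("--seed", "1")))
  paths <- write_fixture(fx, val("--out", "fixtures"))
  cat("wrote:", paths, sep = "\n  ")
  cat("\n")
} else {
  cat("unknown subcommand:", cmd, "\n"); quit(status = 1)
}
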