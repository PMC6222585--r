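#' In-silico verification that a planned knock-in is a putative null
#'
#' Applies the edit plan to the reference ([simulate_hdr()]), rebuilds every
#' isoform's spliced CDS from the edited genome (CDS intervals downstream of
#' the insertion are shifted by the payload length; the interval containing
#' the insertion grows by it), and reports per isoform: the insertion offset
#' within the spliced CDS, the reading-frame phase at the insertion, the
#' offset of the first premature in-frame stop codon, the fraction of the
#' wild-type protein truncated, and the frameshift flag (payload length mod
#' 3 != 0). An isoform whose CDS does not contain the insertion is reported
#' as unaffected rather than an error, supporting deliberate
#' isoform-specific designs. Locus checks are by exact substring search:
#' the original protospacer+PAM must be destroyed (the insertion between
#' protospacer bases 17/18 splits it) and the cassette's exogenous Cas9 site
#' must be installed exactly once in sense orientation.
#'
#' @param gene Wild-type `stopin_gene`.
#' @param plan A knock-in `edit_plan`.
#' @param reference Wild-type `stopin_genome`.
#' @param max_cds_fraction Threshold for the "putative null" label: the
#'   insertion must land within this leading fraction of every isoform's
#'   CDS.
#' @param cassette The cassette used in the plan (default canonical).
#' @return A `verification_report`: `$isoforms` data.frame,
#'   `$original_site_destroyed`, `$exogenous_site_installed`,
#'   `$putative_null`, plus `$edited_genome` and `$edited_gene` for
#'   downstream assay design.
#' @export
verify_knockin <- function(gene, plan, reference, max_cds_fraction = 0.5,
                           cassette = stopin_cassette()) {
  stopifnot(inherits(gene, "stopin_gene"), inherits(plan, "edit_plan"),
            inherits(reference, "stopin_genome"), plan$kind == "knockin")
  edited <- simulate_hdr(reference, plan)
  cut <- plan$cut
  pay_len <- nchar(plan$payload_plus)
  edited_gene <- shift_gene_model(gene, cut, pay_len)

  rows <- lapply(names(gene$isoforms), function(iso) {
    affected <- cut_in_cds(gene, iso, cut)
    if (!affected) {
      return(data.frame(isoform = iso, affected = FALSE,
                        insertion_cds_offset = NA_integer_,
                        insertion_fraction = NA_real_,
                        phase = NA_integer_,
                        first_stop_offset = NA_integer_,
                        truncation_fraction = NA_real_,
                        frameshift = FALSE, stringsAsFactors = FALSE))
    }
    wt_map <- spliced_cds(gene, iso, reference)
    wt_prot <- translate(wt_map$seq)
    wt_aa <- nchar(wt_prot)
    ins_off <- cds_offset_of_cut(wt_map, cut, gene$strand)
    ed_cds <- spliced_cds(edited_gene, iso, edited)$seq
    first_stop <- first_inframe_stop_at_or_after(ed_cds, ins_off)
    intact_aa <- min(ins_off %/% 3L, wt_aa)
    data.frame(isoform = iso, affected = TRUE,
               insertion_cds_offset = ins_off,
               insertion_fraction = ins_off / nchar(wt_map$seq),
               phase = ins_off %% 3L,
               first_stop_offset = first_stop,
               truncation_fraction = 1 - intact_aa / wt_aa,
               frameshift = pay_len %% 3L != 0L,
               stringsAsFactors = FALSE)
  })
  iso_df <- do.call(rbind, rows)

  # locus checks by exact substring search
  g <- plan$guide
  site23 <- paste0(g$protospacer, g$pam)
  destroyed <- genome_match_count(site23, edited) ==
    genome_match_count(site23, reference) - 1L
  exo_plus <- if (gene$strand == "+") substr(cassette$sequence, 1L, 23L)
              else reverse_complement(substr(cassette$sequence, 1L, 23L))
  exo_count <- length(find_all_offsets_fixed(edited$seq[[gene$chrom]],
                                             exo_plus))
  exo_ref <- length(find_all_offsets_fixed(reference$seq[[gene$chrom]],
                                           exo_plus))
  installed <- exo_count == exo_ref + 1L

  null_label <- all(iso_df$affected) &&
    all(iso_df$insertion_fraction <= max_cds_fraction) &&
    all(iso_df$frameshift) && !any(is.na(iso_df$first_stop_offset))

  structure(list(
    isoforms = iso_df,
    original_site_destroyed = destroyed,
    exogenous_site_installed = installed,
    exogenous_site_count = exo_count,
    nhei_unique_in_amplicon = NA,
    putative_null = null_label,
    edited_genome = edited,
    edited_gene = edited_gene
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat("<verification_report>\n")
  print.data.frame(x$isoforms, digits = 3)
  cat("original Cas9 site destroyed:  ", x$original_site_destroyed, "\n")
  cat("exogenous Cas9 site installed: ", x$exogenous_site_installed,
      " (count ", x$exogenous_site_count, ")\n", sep = "")
  cat("putative null:                 ", x$putative_null, "\n")
  invisible(x)
}

# Gene model with coordinates shifted for an insertion of `len` bases at
# plus-strand coordinate `cut`; the CDS interval containing the cut absorbs
# the payload.
#' @keywords internal
#' @noRd
shift_gene_model <- function(gene, cut, len) {
  isoforms <- lapply(gene$isoforms, function(iv) {
    s <- iv$start; e <- iv$end
    data.frame(start = as.integer(ifelse(s >= cut, s + len, s)),
               end = as.integer(ifelse(e > cut, e + len, e)))
  })
  new_gene_model(gene$gene_id, gene$name, gene$chrom, gene$strand, isoforms)
}

# 0-based nt offset of the first in-frame stop codon whose codon is not
# entirely upstream of `from`.
#' @keywords internal
#' @noRd
first_inframe_stop_at_or_after <- function(cds, from) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(NA_integer_)
  starts <- seq(1L, by = 3L, length.out = n)
  codons <- substring(cds, starts, starts + 2L)
  hit <- which(is_stop_codon(codons) & (starts - 1L + 3L) > from)
  if (length(hit)) as.integer(starts[hit[1L]] - 1L) else NA_integer_
}
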