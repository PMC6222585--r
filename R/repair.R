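#' Design a STOP-IN knock-in repair oligo
#'
#' Builds the single-stranded HDR template for inserting the cassette at a
#' guide's cut site. The oligo is written on the chromosome strand carrying
#' the PAM (HDR efficiency favours the PAM strand when the edit is at the
#' cut), with homology arms of `arm_len` bases immediately flanking the cut
#' on that strand. The payload is oriented so that, after repair, the gene's
#' sense strand carries the cassette verbatim: when the PAM strand equals the
#' gene's sense strand the oligo contains the cassette as written, otherwise
#' its reverse complement. Default geometry is 35 + 43 + 35 = 113 nt.
#'
#' @param guide One row of a [find_guides()] result (or an equivalent list
#'   with `chrom`, `start`, `end`, `pam_strand`, `protospacer`, `pam`,
#'   `cut`).
#' @param gene The target `stopin_gene`; its strand fixes the sense
#'   orientation of the payload.
#' @param genome Reference `stopin_genome`.
#' @param arm_len Homology-arm length on each side (default 35).
#' @param cassette A `stopin_cassette`; default canonical.
#' @return A `repair_oligo` object: `full_sequence` (= `arm5 + payload +
#'   arm3`, 5'->3' in synthesis order), `arm5`, `arm3`, `payload`,
#'   `synthesis_strand`, `insertion_point` (plus-strand coordinate),
#'   `chrom`, `target_gene`.
#' @export
design_knockin_oligo <- function(guide, gene, genome, arm_len = 35L,
                                 cassette = stopin_cassette()) {
  stopifnot(inherits(gene, "stopin_gene"), inherits(genome, "stopin_genome"),
            arm_len >= 1L)
  guide <- as.list(guide)
  if (!identical(as.character(guide$chrom), gene$chrom)) {
    stop("guide chromosome does not match gene ", gene$gene_id, call. = FALSE)
  }
  cut <- as.integer(guide$cut)
  if (!any(vapply(names(gene$isoforms), function(id)
    cut_in_cds(gene, id, cut), logical(1)))) {
    stop("guide cut site is not inside any CDS of gene ", gene$gene_id,
         call. = FALSE)
  }
  clen <- chrom_lengths(genome)[[gene$chrom]]
  if (cut - arm_len < 0L || cut + arm_len > clen) {
    stop("cut site closer than arm_len (", arm_len,
         ") to a chromosome end", call. = FALSE)
  }
  up <- genome_seq(genome, gene$chrom, cut - arm_len, cut, "+")
  down <- genome_seq(genome, gene$chrom, cut, cut + arm_len, "+")
  payload_plus <- if (gene$strand == "+") cassette$sequence
                  else reverse_complement(cassette$sequence)
  if (guide$pam_strand == "+") {
    arm5 <- up; arm3 <- down; payload <- payload_plus
  } else {
    arm5 <- reverse_complement(down)
    arm3 <- reverse_complement(up)
    payload <- reverse_complement(payload_plus)
  }
  structure(list(
    full_sequence = paste0(arm5, payload, arm3),
    arm5 = arm5, arm3 = arm3, payload = payload,
    synthesis_strand = guide$pam_strand,
    insertion_point = cut, chrom = gene$chrom,
    target_gene = gene$gene_id,
    kind = "knockin"
  ), class = "repair_oligo")
}

#' @export
print.repair_oligo <- function(x, ...) {
  cat("<repair_oligo> ", x$kind, " for ", x$target_gene, ", ",
      nchar(x$full_sequence), " nt on strand ", x$synthesis_strand,
      " (insertion at ", x$chrom, ":", x$insertion_point, ")\n", sep = "")
  cat("  5'-", x$arm5, "[", x$payload, "]", x$arm3, "-3'\n", sep = "")
  invisible(x)
}

#' Assemble an edit plan from a guide and its repair oligo
#'
#' An `edit_plan` couples a guide, the oligo, and the expected edited
#' sense-strand local sequence, and is what [simulate_hdr()] and
#' [verify_knockin()] consume.
#'
#' @param guide Guide row (as for [design_knockin_oligo()]).
#' @param oligo The matching `repair_oligo`.
#' @param gene The target `stopin_gene`.
#' @param genome Reference genome (used to freeze the expected local edit).
#' @return An `edit_plan` object.
#' @export
edit_plan <- function(guide, oligo, gene, genome) {
  stopifnot(inherits(oligo, "repair_oligo"))
  guide <- as.list(guide)
  cut <- as.integer(guide$cut)
  arm <- nchar(oligo$arm5)
  payload_plus <- if (oligo$synthesis_strand == "+") oligo$payload
                  else reverse_complement(oligo$payload)
  expected_plus <- paste0(
    genome_seq(genome, oligo$chrom, cut - arm, cut, "+"),
    payload_plus,
    genome_seq(genome, oligo$chrom, cut, cut + arm, "+"))
  expected_sense <- if (gene$strand == "+") expected_plus
                    else reverse_complement(expected_plus)
  structure(list(
    guide = guide, oligo = oligo, gene_strand = gene$strand,
    chrom = oligo$chrom, cut = cut, payload_plus = payload_plus,
    expected_local_sense = expected_sense,
    kind = oligo$kind
  ), class = "edit_plan")
}

#' Apply a planned HDR edit to a genome
#'
#' Models perfect, junction-error-free HDR. For a knock-in plan the payload
#' is inserted exactly at the cut coordinate (chromosome grows by the payload
#' length); for a reversion plan the cassette is excised and the chromosome
#' shrinks back by 43. Pre-checks enforce internal consistency: a knock-in
#' requires the intact protospacer+PAM at the recorded span (so applying the
#' same plan twice fails — the first edit destroys the site); a reversion
#' requires the cassette at the recorded span in sense orientation.
#'
#' @param genome Template `stopin_genome`.
#' @param plan An `edit_plan`.
#' @return A new edited `stopin_genome`.
#' @export
simulate_hdr <- function(genome, plan) {
  stopifnot(inherits(genome, "stopin_genome"), inherits(plan, "edit_plan"))
  chrom <- plan$chrom
  clen <- chrom_lengths(genome)[[chrom]]
  if (plan$kind == "knockin") {
    g <- plan$guide
    if (g$start < 0L || g$end > clen) {
      stop("guide span outside chromosome", call. = FALSE)
    }
    site <- genome_seq(genome, chrom, g$start, g$end, g$pam_strand)
    if (site != paste0(g$protospacer, g$pam)) {
      stop("guide site not present in template (already edited?)",
           call. = FALSE)
    }
    seqs <- genome$seq
    s <- seqs[[chrom]]
    seqs[[chrom]] <- paste0(substr(s, 1L, plan$cut),
                            plan$payload_plus,
                            substr(s, plan$cut + 1L, clen))
    return(new_genome(seqs))
  }
  if (plan$kind == "reversion") {
    span_len <- nchar(plan$payload_removed_plus)
    if (plan$cut + span_len > clen) {
      stop("recorded cassette span outside chromosome", call. = FALSE)
    }
    found <- genome_seq(genome, chrom, plan$cut, plan$cut + span_len, "+")
    if (found != plan$payload_removed_plus) {
      stop("cassette not found at recorded position in expected orientation",
           call. = FALSE)
    }
    seqs <- genome$seq
    s <- seqs[[chrom]]
    seqs[[chrom]] <- paste0(substr(s, 1L, plan$cut),
                            substr(s, plan$cut + span_len + 1L, clen))
    return(new_genome(seqs))
  }
  stop("unknown edit plan kind: ", plan$kind, call. = FALSE)
}

#' Design a wild-type reversion oligo for a STOP-IN locus
#'
#' A knocked-in locus can be re-edited back to wild type using the
#' cassette's exogenous Cas9 site: the companion crRNA is the cassette's
#' first 20 nt, and the repair template is contiguous wild-type sequence
#' spanning the insertion point. The oligo is written on the gene's sense
#' strand (the PAM strand of the exogenous site) with `total_len` bases
#' split 5'/3' around the junction (default 71 nt as 35 + 36).
#'
#' @param edited_genome The knocked-in `stopin_genome`.
#' @param chrom Chromosome carrying the insertion.
#' @param sense_strand The gene's sense strand (`"+"`/`"-"`).
#' @param total_len Total oligo length (default 71).
#' @param cassette The cassette that was inserted (default canonical).
#' @return A `repair_oligo` (kind `"reversion"`, empty payload) with an
#'   attribute `crRNA` (the exogenous-site guide sequence) and an attached
#'   reversion `edit_plan` in attribute `plan`.
#' @export
design_reversion_oligo <- function(edited_genome, chrom, sense_strand,
                                   total_len = 71L,
                                   cassette = stopin_cassette()) {
  stopifnot(inherits(edited_genome, "stopin_genome"),
            sense_strand %in% c("+", "-"), total_len >= 2L)
  cas_plus <- if (sense_strand == "+") cassette$sequence
              else reverse_complement(cassette$sequence)
  hits <- find_all_offsets_fixed(edited_genome$seq[[chrom]], cas_plus)
  if (length(hits) != 1L) {
    stop("locus must contain the cassette exactly once in sense ",
         "orientation (found ", length(hits), ")", call. = FALSE)
  }
  ins <- hits[1L]           # plus-strand start of cassette span
  clen <- chrom_lengths(edited_genome)[[chrom]]
  n5 <- total_len %/% 2L    # 35 for the default 71
  n3 <- total_len - n5      # 36
  if (sense_strand == "+") {
    up_len <- n5; down_len <- n3
  } else {
    up_len <- n3; down_len <- n5
  }
  cas_len <- nchar(cas_plus)
  if (ins - up_len < 0L || ins + cas_len + down_len > clen) {
    stop("insertion point closer than the oligo arm to a chromosome end",
         call. = FALSE)
  }
  up <- genome_seq(edited_genome, chrom, ins - up_len, ins, "+")
  down <- genome_seq(edited_genome, chrom, ins + cas_len,
                     ins + cas_len + down_len, "+")
  if (sense_strand == "+") {
    arm5 <- up; arm3 <- down
  } else {
    arm5 <- reverse_complement(down); arm3 <- reverse_complement(up)
  }
  oligo <- structure(list(
    full_sequence = paste0(arm5, arm3),
    arm5 = arm5, arm3 = arm3, payload = "",
    synthesis_strand = sense_strand,
    insertion_point = ins, chrom = chrom,
    target_gene = NA_character_,
    kind = "reversion"
  ), class = "repair_oligo")
  plan <- structure(list(
    guide = list(protospacer = substr(cassette$sequence, 1L, 20L),
                 pam = cassette$pam, pam_strand = sense_strand),
    oligo = oligo, gene_strand = sense_strand, chrom = chrom, cut = ins,
    payload_removed_plus = cas_plus,
    kind = "reversion"
  ), class = "edit_plan")
  attr(oligo, "crRNA") <- substr(cassette$sequence, 1L, 20L)
  attr(oligo, "plan") <- plan
  oligo
}
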