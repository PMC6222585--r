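#' Find candidate Cas9 guide sites in a gene
#'
#' Scans both chromosome strands of the gene's genomic extent for 23-nt
#' windows matching N20-NGG (20-nt protospacer followed by an NGG PAM) and
#' keeps those whose predicted blunt cut — 3 bp 5' of the PAM, between
#' protospacer bases 17 and 18 — falls strictly inside a CDS interval.
#' Windows containing N are skipped. Candidates are then filtered:
#'
#' * `require_all_isoforms`: the cut must lie in the CDS of every isoform
#'   (the shared-exon preference for null designs);
#' * `max_cds_fraction`: the cut must lie within the first fraction of the
#'   shortest covering spliced CDS (early-exon preference, default first
#'   half);
#' * `require_unique`: the 23-mer must occur exactly once genome-wide
#'   (exact-match uniqueness proxy; no mismatch-tolerant off-target search).
#'
#' Results are ranked by ascending `cds_fraction`, ties broken by ascending
#' genomic coordinate, then `+` before `-` strand.
#'
#' @param gene A `stopin_gene`.
#' @param genome A `stopin_genome`.
#' @param require_all_isoforms Require the cut inside every isoform's CDS.
#' @param max_cds_fraction Keep cuts within this leading fraction of the
#'   shortest covering CDS; in (0, 1].
#' @param require_unique Keep only guides whose protospacer+PAM matches the
#'   genome exactly once.
#' @return A `guide_set` data.frame, one row per guide: `protospacer`, `pam`,
#'   `pam_strand`, `chrom`, `start`, `end` (0-based half-open span of
#'   protospacer+PAM on the plus strand), `cut` (plus-strand between-bases
#'   coordinate), `cds_offset`, `cds_fraction`, `isoform_coverage`
#'   (comma-separated), `n_isoforms_hit`, `genome_match_count`.
#' @export
find_guides <- function(gene, genome, require_all_isoforms = TRUE,
                        max_cds_fraction = 0.5, require_unique = TRUE) {
  stopifnot(inherits(gene, "stopin_gene"), inherits(genome, "stopin_genome"))
  stopifnot(max_cds_fraction > 0, max_cds_fraction <= 1)
  all_iv <- do.call(rbind, gene$isoforms)
  if (is.null(all_iv) || nrow(all_iv) == 0L) {
    warning("gene ", gene$gene_id, " has no CDS; no guides", call. = FALSE)
    return(empty_guide_set())
  }
  clen <- chrom_lengths(genome)[[gene$chrom]]
  lo <- max(0L, min(all_iv$start) - 22L)
  hi <- min(clen, max(all_iv$end) + 22L)
  region <- genome_seq(genome, gene$chrom, lo, hi, "+")

  # plus-strand PAM: [ACGT]{21}GG ; minus-strand PAM: CC[ACGT]{21}
  plus_off <- find_all_offsets(region, "[ACGT]{21}GG")
  minus_off <- find_all_offsets(region, "CC[ACGT]{21}")

  rows <- list()
  add_row <- function(start, pam_strand) {
    w <- substr(region, start - lo + 1L, start - lo + 23L)
    if (pam_strand == "+") {
      proto <- substr(w, 1L, 20L); pam <- substr(w, 21L, 23L)
      cut <- start + 17L
    } else {
      wrc <- reverse_complement(w)
      proto <- substr(wrc, 1L, 20L); pam <- substr(wrc, 21L, 23L)
      cut <- start + 6L
    }
    list(protospacer = proto, pam = pam, pam_strand = pam_strand,
         chrom = gene$chrom, start = start, end = start + 23L, cut = cut)
  }
  for (o in plus_off) rows[[length(rows) + 1L]] <- add_row(lo + o, "+")
  for (o in minus_off) rows[[length(rows) + 1L]] <- add_row(lo + o, "-")
  if (length(rows) == 0L) return(empty_guide_set())

  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  # isoform coverage and CDS position of each cut
  iso_ids <- names(gene$isoforms)
  maps <- lapply(iso_ids, function(id) spliced_cds(gene, id, genome))
  names(maps) <- iso_ids
  iso_len <- vapply(maps, function(m) nchar(m$seq), integer(1))

  cov <- character(nrow(df)); nhit <- integer(nrow(df))
  frac <- rep(NA_real_, nrow(df)); offs <- rep(NA_integer_, nrow(df))
  for (i in seq_len(nrow(df))) {
    hit <- iso_ids[vapply(iso_ids, function(id)
      cut_in_cds(gene, id, df$cut[i]), logical(1))]
    cov[i] <- paste(hit, collapse = ",")
    nhit[i] <- length(hit)
    if (length(hit)) {
      shortest <- hit[which.min(iso_len[hit])]
      off <- cds_offset_of_cut(maps[[shortest]], df$cut[i], gene$strand)
      offs[i] <- off
      frac[i] <- off / iso_len[[shortest]]
    }
  }
  df$cds_offset <- offs
  df$cds_fraction <- frac
  df$isoform_coverage <- cov
  df$n_isoforms_hit <- nhit

  df <- df[df$n_isoforms_hit > 0L, , drop = FALSE]
  if (require_all_isoforms) {
    df <- df[df$n_isoforms_hit == length(iso_ids), , drop = FALSE]
  }
  df <- df[!is.na(df$cds_fraction) & df$cds_fraction <= max_cds_fraction, ,
           drop = FALSE]
  if (nrow(df)) {
    df$genome_match_count <- vapply(seq_len(nrow(df)), function(i)
      genome_match_count(paste0(df$protospacer[i], df$pam[i]), genome),
      integer(1))
    if (require_unique) {
      df <- df[df$genome_match_count == 1L, , drop = FALSE]
    }
  } else {
    df$genome_match_count <- integer(0)
  }
  if (nrow(df)) {
    df <- df[order(df$cds_fraction, df$start,
                   match(df$pam_strand, c("+", "-"))), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("guide_set", "data.frame")
  df
}

#' @keywords internal
#' @noRd
empty_guide_set <- function() {
  df <- data.frame(protospacer = character(0), pam = character(0),
                   pam_strand = character(0), chrom = character(0),
                   start = integer(0), end = integer(0), cut = integer(0),
                   cds_offset = integer(0), cds_fraction = numeric(0),
                   isoform_coverage = character(0),
                   n_isoforms_hit = integer(0),
                   genome_match_count = integer(0))
  class(df) <- c("guide_set", "data.frame")
  df
}

#' Predicted Cas9 cut coordinate of a guide site
#'
#' Cas9 cuts bluntly 3 bp 5' of the PAM, between protospacer bases 17 and
#' 18. The returned value is a plus-strand between-bases coordinate: the
#' insertion point sits between genomic bases `cut - 1` and `cut`.
#'
#' @param start,end 0-based half-open plus-strand span of the 23-nt
#'   protospacer+PAM window.
#' @param pam_strand `"+"` or `"-"`: chromosome strand carrying the PAM.
#' @return Integer plus-strand cut coordinate.
#' @examples
#' cut_site(100, 123, "+")  # 117
#' cut_site(100, 123, "-")  # 106
#' @export
cut_site <- function(start, end, pam_strand) {
  stopifnot(end - start == 23L, pam_strand %in% c("+", "-"))
  if (pam_strand == "+") start + 17L else start + 6L
}

#' Exact genome-wide occurrence count of a protospacer+PAM
#'
#' Counts exact (possibly overlapping) matches of the 23-mer on both strands
#' of every chromosome. A count of 1 is the uniqueness criterion used by
#' [find_guides()]; this is an exact-match proxy, not a mismatch-tolerant
#' off-target search.
#'
#' @param site 23-nt protospacer+PAM string.
#' @param genome A `stopin_genome`.
#' @return Non-negative integer.
#' @export
genome_match_count <- function(site, genome) {
  stopifnot(inherits(genome, "stopin_genome"))
  site <- toupper(site)
  if (nchar(site) != 23L) stop("query must be 23 nt", call. = FALSE)
  rc <- reverse_complement(site)
  n <- 0L
  for (chrom_seq in genome$seq) {
    n <- n + length(find_all_offsets_fixed(chrom_seq, site)) +
      length(find_all_offsets_fixed(chrom_seq, rc))
  }
  n
}
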