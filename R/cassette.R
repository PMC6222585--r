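#' The canonical 43-nt STOP-IN cassette
#'
#' The universal knock-in cassette
#' `GGGAAGTTTGTCCAGAGCAGAGGTGACTAAGTGATAAGCTAGC` combines, in 43 nt:
#' an exogenous Cas9 target site (20-nt protospacer + AGG PAM, first 23 nt),
#' stop codons in all three reading frames, a net +1 frameshift
#' (43 mod 3 = 1), the reverse complement of the universal inner genotyping
#' primer, and a terminal NheI site (`GCTAGC`) for RFLP detection. Inserted
#' into coding sequence it truncates translation in every phase and
#' frameshifts any readthrough product, so the edit is a putative null
#' regardless of the insertion frame.
#'
#' All sub-feature spans are 0-based half-open offsets into the cassette.
#'
#' @param sequence Cassette sequence; default is the canonical constant.
#'   Supplying a variant builds a `stopin_cassette` whose sub-features are
#'   located by search where possible (use [verify_cassette_integrity()] to
#'   check a variant keeps the null-generating core).
#' @return A `stopin_cassette` object.
#' @examples
#' cas <- stopin_cassette()
#' nchar(cas$sequence)  # 43
#' @export
stopin_cassette <- function(sequence = STOPIN_CASSETTE_SEQ) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  rc_primer <- reverse_complement(UNIVERSAL_INNER_PRIMER)
  primer_off <- find_all_offsets_fixed(sequence, rc_primer)
  nhei_off <- find_all_offsets_fixed(sequence, "GCTAGC")
  structure(list(
    sequence = sequence,
    length = n,
    exogenous_target = c(start = 0L, end = min(23L, n)),
    protospacer = substr(sequence, 1L, 20L),
    pam = substr(sequence, 21L, 23L),
    stop_positions = stop_offsets_by_frame(sequence),
    nhei_span = if (length(nhei_off)) c(start = nhei_off[1L],
                                        end = nhei_off[1L] + 6L) else NULL,
    universal_primer_site = if (length(primer_off))
      c(start = primer_off[1L], end = primer_off[1L] + nchar(rc_primer))
      else NULL,
    net_frameshift = n %% 3L
  ), class = "stopin_cassette")
}

#' @rdname stopin_cassette
#' @format `STOPIN_CASSETTE_SEQ` is the 43-nt cassette string.
#' @export
STOPIN_CASSETTE_SEQ <- "GGGAAGTTTGTCCAGAGCAGAGGTGACTAAGTGATAAGCTAGC"

#' @export
print.stopin_cassette <- function(x, ...) {
  cat("<stopin_cassette> ", x$length, " nt, net frameshift +",
      x$net_frameshift, "\n  5'-", x$sequence, "-3'\n", sep = "")
  cat("  exogenous Cas9 site: ", x$protospacer, " + PAM ", x$pam, "\n",
      sep = "")
  for (f in 1:3) {
    cat("  reading frame ", f, ": ",
        length(x$stop_positions[[f]]), " stop codon(s)\n", sep = "")
  }
  if (!is.null(x$nhei_span)) {
    cat("  NheI site at offset ", x$nhei_span[["start"]], "\n", sep = "")
  }
  invisible(x)
}

# 0-based offsets of stop codons per frame (frames keyed "1","2","3" for
# reporting; frame f scans non-overlapping codons starting at offset f-1).
#' @keywords internal
#' @noRd
stop_offsets_by_frame <- function(seq) {
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    starts <- seq.int(f + 1L, by = 3L,
                      length.out = max(0L, (n - f) %/% 3L))
    codons <- substring(seq, starts, starts + 2L)
    out[[as.character(f + 1L)]] <- as.integer(starts[is_stop_codon(codons)] - 1L)
  }
  out
}

#' Reading-frame report for a sequence
#'
#' Scans non-overlapping codons in each of the three frames (offsets 0, 1, 2)
#' and reports stop-codon counts (TAA/TAG/TGA), the offset of the first stop
#' per frame, and the net frameshift (`length mod 3`). On the canonical
#' cassette this reproduces the defining anatomy: frames 1 and 2 carry two
#' stop codons each, frame 3 carries one, net frameshift +1.
#'
#' @param seq Nucleotide string, length >= 3.
#' @return A `frame_report`: data.frame with columns `frame` (1-3),
#'   `n_stops`, `first_stop_offset` (0-based, `NA` if none), plus attribute
#'   `net_frameshift`.
#' @export
frame_report <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  offs <- stop_offsets_by_frame(seq)
  rep <- data.frame(
    frame = 1:3,
    n_stops = vapply(offs, length, integer(1)),
    first_stop_offset = vapply(offs, function(o)
      if (length(o)) o[1L] else NA_integer_, integer(1)),
    row.names = NULL)
  attr(rep, "net_frameshift") <- nchar(seq) %% 3L
  class(rep) <- c("frame_report", "data.frame")
  rep
}

#' @export
print.frame_report <- function(x, ...) {
  print.data.frame(x)
  cat("net frameshift:", attr(x, "net_frameshift"), "\n")
  invisible(x)
}

#' Check a cassette's structural invariants
#'
#' For the canonical cassette, checks the full anatomy (exact sequence,
#' length 43, sub-feature positions). For a user-supplied variant, checks
#' only the modification-tolerant core that makes any cassette a null
#' generator: at least one stop codon in every reading frame, a length not
#' divisible by 3, an exogenous target ending in GG (NGG PAM), and a unique
#' restriction site.
#'
#' @param cassette A `stopin_cassette`.
#' @param canonical If `TRUE` (default when the sequence equals the packaged
#'   constant), also check canonical-only invariants.
#' @return A `cassette_check` data.frame with columns `check` and `pass`;
#'   attribute `ok` is `TRUE` when every check passes.
#' @export
verify_cassette_integrity <- function(cassette,
                                      canonical =
                                        cassette$sequence == STOPIN_CASSETTE_SEQ) {
  stopifnot(inherits(cassette, "stopin_cassette"))
  s <- cassette$sequence
  checks <- c(
    stop_in_every_frame = all(vapply(cassette$stop_positions, length,
                                     integer(1)) >= 1L),
    frameshift = nchar(s) %% 3L != 0L,
    exogenous_target_ngg = grepl("GG$", cassette$pam),
    restriction_site_unique =
      length(find_all_offsets_fixed(s, "GCTAGC")) == 1L
  )
  if (canonical) {
    checks <- c(checks,
      canonical_sequence = s == STOPIN_CASSETTE_SEQ,
      length_43 = nchar(s) == 43L,
      nhei_at_3prime = !is.null(cassette$nhei_span) &&
        cassette$nhei_span[["end"]] == nchar(s),
      universal_primer_site_present = !is.null(cassette$universal_primer_site),
      stop_counts_2_2_1 = identical(
        unname(vapply(cassette$stop_positions, length, integer(1))),
        c(2L, 2L, 1L))
    )
  }
  out <- data.frame(check = names(checks), pass = unname(checks),
                    row.names = NULL)
  attr(out, "ok") <- all(checks)
  class(out) <- c("cassette_check", "data.frame")
  out
}

#' @export
print.cassette_check <- function(x, ...) {
  print.data.frame(x)
  cat(if (attr(x, "ok")) "all checks pass\n" else "FAILED checks present\n")
  invisible(x)
}
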