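#' Reverse complement of a nucleotide sequence
#'
#' Alphabet is restricted to A, C, G, T, N; N complements to N. The operation
#' is an involution: `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq Single nucleotide string (A/C/G/T/N, case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("GCTAGC")   # palindromic NheI site
#' reverse_complement("ACGTN")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside the A/C/G/T/N alphabet",
         call. = FALSE)
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code (from [Biostrings::GENETIC_CODE]);
#' translation stops at the first stop codon, a trailing partial codon is
#' ignored, and any codon containing a non-ACGT character (including N)
#' translates to `X`.
#'
#' @param cds Nucleotide string, length >= 3.
#' @return Amino-acid string (no trailing `*`).
#' @examples
#' translate("ATGTAA")  # "M"
#' @export
translate <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("coding sequence shorter than one codon", call. = FALSE)
  n_codon <- nchar(cds) %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

#' @keywords internal
#' @noRd
is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# All (possibly overlapping) 0-based start offsets of `pattern` in `subject`.
# Uses a zero-width lookahead so overlapping hits are all reported.
#' @keywords internal
#' @noRd
find_all_offsets <- function(subject, pattern) {
  if (nchar(pattern) == 0L || nchar(subject) < nchar(pattern)) return(integer(0))
  rx <- paste0("(?=", pattern, ")")
  m <- gregexpr(rx, subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

# Literal overlapping search; patterns here are always plain nucleotide
# strings, so no regex metacharacters need escaping.
#' @keywords internal
#' @noRd
find_all_offsets_fixed <- function(subject, pattern) {
  stopifnot(!grepl("[^A-Za-z]", pattern))
  find_all_offsets(subject, pattern)
}
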