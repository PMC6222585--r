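#' Load a reference genome from FASTA
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet.
#' All coordinates used by this package are 0-based half-open on the plus
#' strand; conversion from 1-based formats (GFF3) happens at the I/O boundary.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `stopin_genome` object (named list of chromosome strings).
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(fasta_path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA (", fasta_path, "): ", conditionMessage(e),
           call. = FALSE)
    }
  )
  seqs <- toupper(as.character(set))
  # record names may carry descriptions after whitespace
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    stop("duplicate FASTA record name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record(s): ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    offender <- names(seqs)[bad][1L]
    # locate the first offending line for the error message
    lines <- readLines(fasta_path, warn = FALSE)
    hit <- which(!startsWith(lines, ">") &
                   grepl("[^ACGTNacgtn[:space:]]", lines))
    where <- if (length(hit)) paste0(" (line ", hit[1L], ")") else ""
    stop("record '", offender, "' contains characters outside A/C/G/T/N",
         where, call. = FALSE)
  }
  new_genome(seqs)
}

#' @keywords internal
#' @noRd
new_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  structure(list(seq = seqs), class = "stopin_genome")
}

#' Construct a genome from in-memory sequences
#'
#' @param seqs Named character vector of chromosome sequences.
#' @return A `stopin_genome`.
#' @export
genome_from_sequences <- function(seqs) {
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) ||
      any(names(seqs) == "")) {
    stop("sequences must have unique non-empty names", call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence supplied", call. = FALSE)
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  new_genome(seqs)
}

#' Chromosome lengths of a genome
#' @param genome A `stopin_genome`.
#' @return Named integer vector.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "stopin_genome"))
  vapply(genome$seq, nchar, integer(1))
}

#' Extract genomic sequence
#'
#' Half-open 0-based coordinates; a minus-strand query returns the reverse
#' complement of the plus-strand slice. Exactly `end - start` characters are
#' returned.
#'
#' @param genome A `stopin_genome`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open span, `0 <= start < end <= length`.
#' @param strand `"+"` or `"-"`.
#' @return Nucleotide string.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  stopifnot(inherits(genome, "stopin_genome"))
  if (!chrom %in% names(genome$seq)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  len <- nchar(genome$seq[[chrom]])
  if (!(start >= 0 && start < end && end <= len)) {
    stop(sprintf("span [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len), call. = FALSE)
  }
  s <- substr(genome$seq[[chrom]], start + 1L, end)
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' @export
print.stopin_genome <- function(x, ...) {
  len <- chrom_lengths(x)
  cat("<stopin_genome> ", length(len), " sequence(s), ",
      format(sum(len), big.mark = ","), " bp total\n", sep = "")
  for (nm in names(len)) cat("  ", nm, ": ", len[[nm]], " bp\n", sep = "")
  invisible(x)
}

#' Write a genome to FASTA text
#'
#' @param genome A `stopin_genome`.
#' @param path Output file; if `NULL`, the FASTA text is returned invisibly
#'   as a character vector of lines.
#' @param width Line-wrap width.
#' @return Invisibly, the FASTA lines.
#' @export
write_genome_fasta <- function(genome, path = NULL, width = 70L) {
  stopifnot(inherits(genome, "stopin_genome"))
  lines <- unlist(lapply(names(genome$seq), function(nm) {
    s <- genome$seq[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", nm), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
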