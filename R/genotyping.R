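#' The universal inner genotyping primer (oHP013r)
#'
#' The common reverse inner primer whose reverse complement lies inside the
#' STOP-IN cassette, so it amplifies only cassette-carrying templates when
#' paired with a gene-specific forward outer primer.
#'
#' @return 25-nt primer string `GCTTATCACTTAGTCACCTCTGCTC`.
#' @export
universal_inner_primer <- function() UNIVERSAL_INNER_PRIMER

#' @keywords internal
#' @noRd
UNIVERSAL_INNER_PRIMER <- "GCTTATCACTTAGTCACCTCTGCTC"

#' Nearest-neighbor melting temperature of a primer
#'
#' SantaLucia (1998) unified nearest-neighbor parameters with the salt
#' correction applied to the entropy term. Defaults: 50 mM monovalent
#' cation, 250 nM total oligo.
#'
#' @param primer Primer sequence (ACGT).
#' @param na_mM Monovalent salt, mM.
#' @param oligo_nM Total oligo concentration, nM.
#' @return Melting temperature in degrees Celsius.
#' @export
primer_tm <- function(primer, na_mM = 50, oligo_nM = 250) {
  primer <- toupper(primer)
  if (grepl("[^ACGT]", primer) || nchar(primer) < 2L) {
    stop("primer must be ACGT and at least 2 nt", call. = FALSE)
  }
  nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
             TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
             GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
             CC = -8.0)
  nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
             TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
             GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
             CC = -19.9)
  n <- nchar(primer)
  steps <- substring(primer, 1:(n - 1L), 2:n)
  dh <- sum(nn_dh[steps])                       # kcal/mol
  ds <- sum(nn_ds[steps])                       # cal/mol/K
  ends <- substring(primer, c(1L, n), c(1L, n))
  for (b in ends) {
    if (b %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  r <- 1.987
  dh * 1000 / (ds + r * log(oligo_nM * 1e-9 / 4)) - 273.15
}

#' @keywords internal
#' @noRd
gc_percent <- function(seq) {
  100 * lengths(regmatches(seq, gregexpr("[GC]", seq))) / nchar(seq)
}

#' In-silico PCR
#'
#' Exact-match primer binding only (no mismatch tolerance). The forward and
#' reverse primers must bind opposite strands in convergent orientation;
#' product size is measured from the 5' end of the forward binding site to
#' the 5' end of the reverse binding site, inclusive (both primer footprints
#' counted). Either primer may physically bind either strand; all convergent
#' pairings up to `max_product` are reported.
#'
#' @param template A `stopin_genome` (or single chromosome string).
#' @param forward,reverse Primer sequences (>= 15 nt).
#' @param max_product Maximum product size reported (default 5000).
#' @return Data.frame with `chrom`, `start`, `end` (0-based half-open span
#'   of the product on the plus strand) and `size`; zero rows if no product.
#' @export
simulate_pcr <- function(template, forward, reverse, max_product = 5000L) {
  if (is.character(template)) {
    template <- genome_from_sequences(c(amplicon = template))
  }
  stopifnot(inherits(template, "stopin_genome"))
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) < 15L || nchar(reverse) < 15L) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  out <- list()
  for (chrom in names(template$seq)) {
    s <- template$seq[[chrom]]
    # plus-strand binders extend rightward; minus-strand binders leftward
    for (pr in list(list(seq = forward, mate = reverse),
                    list(seq = reverse, mate = forward))) {
      plus_hits <- find_all_offsets_fixed(s, pr$seq)
      mate_rc_hits <- find_all_offsets_fixed(s, reverse_complement(pr$mate))
      for (f in plus_hits) {
        for (m in mate_rc_hits) {
          size <- (m + nchar(pr$mate)) - f
          if (size >= nchar(pr$seq) && size >= nchar(pr$mate) &&
              size <= max_product && m >= f) {
            out[[length(out) + 1L]] <- data.frame(
              chrom = chrom, start = f, end = f + size, size = size,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (forward == reverse) break
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), size = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$start, res$size), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' NheI restriction digest of an amplicon
#'
#' Cuts every `GCTAGC` site between positions 1 and 2 (G^CTAGC). Fragment
#' sizes always sum to the amplicon length.
#'
#' @param amplicon Nucleotide string.
#' @return Integer vector of fragment sizes, 5' to 3'.
#' @examples
#' nhei_digest("GCTAGC")  # 1 5
#' @export
nhei_digest <- function(amplicon) {
  amplicon <- toupper(amplicon)
  n <- nchar(amplicon)
  sites <- find_all_offsets_fixed(amplicon, "GCTAGC")
  cuts <- sort(unique(sites + 1L))
  cuts <- cuts[cuts > 0L & cuts < n]
  bounds <- c(0L, cuts, n)
  as.integer(diff(bounds))
}

#' Design gene-specific outer genotyping primers around an insertion
#'
#' Picks the P1 (forward, upstream) / P3 (reverse, downstream) outer primer
#' pair of the PCR screen: both 18-25 nt, GC 40-60%, nearest-neighbor Tm
#' 52-62 C, each an exact-match singleton within a +/-5 kb window, product
#' spanning the insertion with wild-type size under the cap (default
#' 500 bp, so the 43-bp knock-in shift is resolvable on a gel). The choice
#' is deterministic: best combined score (Tm balance, Tm distance from
#' 60 C, GC distance from 50%), ties broken by smallest product. Primers are
#' designed on the gene's sense strand; the knock-in product is the
#' wild-type product plus the cassette length.
#'
#' @param genome Wild-type `stopin_genome`.
#' @param chrom Chromosome.
#' @param insertion_point Plus-strand between-bases insertion coordinate.
#' @param sense_strand Gene sense strand (primers reported 5'->3' on it).
#' @param product_cap Maximum wild-type product size (default 500).
#' @param primer_len Min/max primer length.
#' @param gc_range Allowed GC%, inclusive.
#' @param tm_range Allowed Tm (C), inclusive.
#' @param unique_window Half-width of the uniqueness window (bp).
#' @param search_span How far from the insertion each primer's 5' end may
#'   lie (bounded by `product_cap`).
#' @param cassette_len Insertion size added to the knock-in product.
#' @return A `primer_pair`: `p1`, `p3`, spans, Tm/GC, `wt_product_size`,
#'   `ki_product_size`, `p2` (universal inner primer) and
#'   `p2_product_size` (P1+P2 product on the knock-in template).
#'   If no pair satisfies the constraints, an error of class
#'   `stopin_design_failure` names the violated constraint(s).
#' @export
pick_outer_primers <- function(genome, chrom, insertion_point,
                               sense_strand = "+",
                               product_cap = 500L,
                               primer_len = c(18L, 25L),
                               gc_range = c(40, 60),
                               tm_range = c(52, 62),
                               unique_window = 5000L,
                               search_span = NULL,
                               cassette_len = 43L) {
  stopifnot(inherits(genome, "stopin_genome"), sense_strand %in% c("+", "-"))
  clen <- chrom_lengths(genome)[[chrom]]
  ins <- as.integer(insertion_point)
  if (ins < 200L || clen - ins < 200L) {
    stop("need at least 200 bp of reference on each side of the insertion",
         call. = FALSE)
  }
  if (is.null(search_span)) {
    search_span <- min(product_cap - 1L, 240L)
  }
  # sense-strand local view centred on the insertion
  view_lo <- max(0L, ins - search_span)
  view_hi <- min(clen, ins + search_span)
  local <- genome_seq(genome, chrom, view_lo, view_hi, sense_strand)
  # offset of the insertion point within the local view
  ins_local <- if (sense_strand == "+") ins - view_lo else view_hi - ins

  enumerate <- function(side) {
    cands <- list()
    for (len in seq(primer_len[1L], primer_len[2L])) {
      if (side == "fwd") {
        starts <- seq_len(max(0L, ins_local - len + 1L))  # end <= ins_local
        starts <- starts[starts + len - 1L <= ins_local]
      } else {
        starts <- seq(ins_local + 1L, nchar(local) - len + 1L)
        starts <- starts[starts >= ins_local + 1L]
      }
      if (!length(starts)) next
      seqs <- substring(local, starts, starts + len - 1L)
      keep <- !grepl("N", seqs, fixed = TRUE)
      if (!any(keep)) next
      cands[[length(cands) + 1L]] <- data.frame(
        start_local = starts[keep] - 1L, len = len, seq = seqs[keep],
        stringsAsFactors = FALSE)
    }
    if (!length(cands)) return(NULL)
    do.call(rbind, cands)
  }
  fail <- function(which) {
    stop(structure(class = c("stopin_design_failure", "error", "condition"),
                   list(message = paste0(
                     "primer design failed; violated constraint(s): ",
                     paste(which, collapse = ", ")), call = NULL)))
  }
  fwd <- enumerate("fwd"); rev_ <- enumerate("rev")
  if (is.null(fwd) || is.null(rev_)) fail("search window")

  filter_side <- function(df) {
    df$gc <- gc_percent(df$seq)
    df <- df[df$gc >= gc_range[1L] & df$gc <= gc_range[2L], , drop = FALSE]
    violated <- character(0)
    if (!nrow(df)) return(list(df = df, violated = "GC content"))
    df$tm <- vapply(df$seq, primer_tm, numeric(1))
    df <- df[df$tm >= tm_range[1L] & df$tm <= tm_range[2L], , drop = FALSE]
    if (!nrow(df)) return(list(df = df, violated = "melting temperature"))
    list(df = df, violated = violated)
  }
  ff <- filter_side(fwd); rf <- filter_side(rev_)
  if (!nrow(ff$df)) fail(ff$violated)
  if (!nrow(rf$df)) fail(rf$violated)
  fwd <- ff$df; rev_ <- rf$df

  # uniqueness in a +/- unique_window around the insertion, both strands
  win_lo <- max(0L, ins - unique_window)
  win_hi <- min(clen, ins + unique_window)
  win <- genome_seq(genome, chrom, win_lo, win_hi, "+")
  is_unique <- function(p) {
    length(find_all_offsets_fixed(win, p)) +
      length(find_all_offsets_fixed(win, reverse_complement(p))) == 1L
  }
  fwd <- fwd[vapply(fwd$seq, is_unique, logical(1)), , drop = FALSE]
  rev_ <- rev_[vapply(rev_$seq, is_unique, logical(1)), , drop = FALSE]
  if (!nrow(fwd) || !nrow(rev_)) fail("uniqueness")

  # pair scoring: wild-type product from forward 5' to reverse 5' inclusive
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    f <- fwd[i, ]
    prod <- (rev_$start_local + rev_$len) - f$start_local
    ok <- prod <= product_cap
    if (!any(ok)) next
    r_ok <- rev_[ok, , drop = FALSE]; prod <- prod[ok]
    score <- abs(f$tm - r_ok$tm) + abs(f$tm - 60) / 2 + abs(r_ok$tm - 60) / 2 +
      abs(f$gc - 50) / 10 + abs(r_ok$gc - 50) / 10
    j <- order(score, prod)[1L]
    cand <- list(f = f, r = r_ok[j, ], prod = prod[j], score = score[j])
    if (is.null(best) || cand$score < best$score ||
        (cand$score == best$score && cand$prod < best$prod)) best <- cand
  }
  if (is.null(best)) fail("product size cap")

  p1 <- best$f$seq
  p3_sense_span <- c(best$r$start_local, best$r$start_local + best$r$len)
  p3 <- reverse_complement(best$r$seq)  # reverse primer reported 5'->3'
  to_plus <- function(lo_local, hi_local) {
    if (sense_strand == "+") c(view_lo + lo_local, view_lo + hi_local)
    else c(view_hi - hi_local, view_hi - lo_local)
  }
  p1_span <- to_plus(best$f$start_local, best$f$start_local + best$f$len)
  p3_span <- to_plus(p3_sense_span[1L], p3_sense_span[2L])
  p2 <- universal_inner_primer()
  # P1 + P2 product on the knock-in template: P2's binding site ends at
  # cassette offset 39; with the cassette inserted at `ins`, the product runs
  # from P1's 5' end to the 3' end of the reverse-complement footprint.
  cas <- stopin_cassette()
  p2_end_in_cassette <- cas$universal_primer_site[["end"]]
  p1_to_ins <- ins_local - best$f$start_local
  p2_product <- p1_to_ins + p2_end_in_cassette

  structure(list(
    p1 = p1, p3 = p3,
    p1_span = p1_span, p3_span = p3_span,
    p1_tm = best$f$tm, p3_tm = best$r$tm,
    p1_gc = best$f$gc, p3_gc = best$r$gc,
    wt_product_size = best$prod,
    ki_product_size = best$prod + cassette_len,
    p2 = p2, p2_product_size = p2_product,
    sense_strand = sense_strand, chrom = chrom,
    insertion_point = ins
  ), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("<primer_pair> ", x$chrom, ":", x$insertion_point, " (sense ",
      x$sense_strand, ")\n", sep = "")
  cat(sprintf("  P1 (fwd outer): %s  Tm %.1fC GC %.0f%%\n", x$p1, x$p1_tm,
              x$p1_gc))
  cat(sprintf("  P3 (rev outer): %s  Tm %.1fC GC %.0f%%\n", x$p3, x$p3_tm,
              x$p3_gc))
  cat("  P2 (universal inner):", x$p2, "\n")
  cat("  products: WT ", x$wt_product_size, " bp, KI ", x$ki_product_size,
      " bp (+", x$ki_product_size - x$wt_product_size, "), P1+P2 ",
      x$p2_product_size, " bp\n", sep = "")
  invisible(x)
}

#' Call an F1 genotype from the two screening reactions
#'
#' Implements the two-reaction logic of the screen: reaction 1 is the
#' gene-specific forward outer primer plus the universal inner primer
#' (product only from cassette-carrying alleles); reaction 2 is the outer
#' primer pair (wild-type band, knock-in band 43 bp larger, or both).
#'
#' * inner product present, both outer bands: heterozygous knock-in;
#' * inner present, only the larger outer band: homozygous candidate,
#'   flagged for confirmation in the next generation (could be a
#'   heterozygote whose second allele deleted a primer site);
#' * inner absent, wild-type band only: wild type;
#' * anything else: ambiguous.
#'
#' @param outer_bands Numeric vector of product sizes from the outer-pair
#'   reaction.
#' @param inner_bands Numeric vector of product sizes from the P1+P2
#'   reaction (empty = no product).
#' @param wt_size,ki_size Expected wild-type and knock-in outer product
#'   sizes.
#' @param tol Band-size matching tolerance in bp (default 0: exact).
#' @return List with `genotype` (one of `"wild-type"`,
#'   `"heterozygous KI"`, `"homozygous KI candidate"`, `"ambiguous"`) and
#'   `confirm_next_generation` flag.
#' @export
classify_f1 <- function(outer_bands, inner_bands, wt_size, ki_size,
                        tol = 0) {
  has <- function(bands, size) any(abs(bands - size) <= tol)
  inner_present <- length(inner_bands) > 0L
  wt_band <- has(outer_bands, wt_size)
  ki_band <- has(outer_bands, ki_size)
  unexpected <- length(outer_bands) &&
    !all(vapply(outer_bands,
                function(b) abs(b - wt_size) <= tol || abs(b - ki_size) <= tol,
                logical(1)))
  genotype <- if (unexpected) "ambiguous"
    else if (inner_present && wt_band && ki_band) "heterozygous KI"
    else if (inner_present && ki_band && !wt_band) "homozygous KI candidate"
    else if (!inner_present && wt_band && !ki_band) "wild-type"
    else "ambiguous"
  list(genotype = genotype,
       confirm_next_generation = genotype == "homozygous KI candidate")
}
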