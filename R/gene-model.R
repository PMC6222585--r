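#' Gene models from GFF3 annotation
#'
#' Reads gene -> mRNA -> CDS features (via `Parent` attributes) and converts
#' the GFF3 1-based inclusive coordinates to the package-wide 0-based
#' half-open convention. CDS phase columns are ignored and recomputed from
#' structure where needed. Within each isoform, CDS intervals are stored in
#' transcription order (descending genomic coordinate for minus-strand
#' genes). mRNAs without CDS features are skipped with a warning; features
#' outside the genome bounds or on unknown chromosomes are errors.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param genome A `stopin_genome`, used for bounds checking.
#' @return Named list of `stopin_gene` objects (names are gene IDs).
#' @export
load_annotation <- function(gff3_path, genome) {
  stopifnot(inherits(genome, "stopin_genome"))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))

  lens <- chrom_lengths(genome)
  unknown <- setdiff(unique(df$seqnames), names(lens))
  if (length(unknown)) {
    stop("annotation references unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  oob <- df$start < 1L | df$end > lens[df$seqnames]
  if (any(oob)) {
    stop("feature(s) outside genome bounds on ",
         paste(unique(df$seqnames[oob]), collapse = ", "), call. = FALSE)
  }

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  orphan <- !cds$Parent %in% mrnas$ID
  if (any(orphan)) {
    stop("CDS feature(s) with unknown Parent mRNA: ",
         paste(unique(cds$Parent[orphan]), collapse = ", "), call. = FALSE)
  }

  out <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    g_mrnas <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g$ID, , drop = FALSE]
    isoforms <- list()
    for (mi in seq_len(nrow(g_mrnas))) {
      m <- g_mrnas[mi, ]
      m_cds <- cds[cds$Parent == m$ID, , drop = FALSE]
      if (nrow(m_cds) == 0L) {
        warning("mRNA '", m$ID, "' has no CDS features; skipped",
                call. = FALSE)
        next
      }
      # to 0-based half-open, then transcription order
      iv <- data.frame(start = m_cds$start - 1L, end = m_cds$end,
                       stringsAsFactors = FALSE)
      iv <- iv[order(iv$start, decreasing = (g$strand == "-")), , drop = FALSE]
      rownames(iv) <- NULL
      if (nrow(iv) > 1L) {
        ss <- sort(iv$start)
        ee <- sort(iv$end)
        if (any(ee[-length(ee)] > ss[-1L])) {
          stop("overlapping CDS intervals in isoform '", m$ID, "'",
               call. = FALSE)
        }
      }
      isoforms[[m$ID]] <- iv
    }
    if (length(isoforms) == 0L) next
    out[[g$ID]] <- new_gene_model(
      gene_id = g$ID,
      name = if (!is.null(g$Name) && !is.na(g$Name)) g$Name else NA_character_,
      chrom = g$seqnames, strand = g$strand, isoforms = isoforms)
  }
  out
}

#' Construct a gene model in memory
#'
#' @param gene_id Gene identifier.
#' @param name Optional alias (e.g. a *C. elegans* gene name such as `aex-2`).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param isoforms Named list; each element a data.frame with 0-based
#'   half-open `start`/`end` CDS intervals in transcription order.
#' @return A `stopin_gene`.
#' @export
new_gene_model <- function(gene_id, name = NA_character_, chrom, strand,
                           isoforms) {
  stopifnot(strand %in% c("+", "-"), length(isoforms) >= 1L,
            !is.null(names(isoforms)))
  for (nm in names(isoforms)) {
    iv <- isoforms[[nm]]
    stopifnot(all(c("start", "end") %in% names(iv)), all(iv$end > iv$start))
    ord <- order(iv$start, decreasing = (strand == "-"))
    if (!identical(ord, seq_len(nrow(iv)))) {
      stop("isoform '", nm, "' CDS intervals not in transcription order",
           call. = FALSE)
    }
  }
  structure(list(gene_id = gene_id, name = name, chrom = chrom,
                 strand = strand, isoforms = isoforms),
            class = "stopin_gene")
}

#' Look up a gene by ID or Name alias
#' @param genes List returned by [load_annotation()].
#' @param id Gene ID or Name.
#' @return A `stopin_gene`.
#' @export
find_gene <- function(genes, id) {
  if (id %in% names(genes)) return(genes[[id]])
  aliases <- vapply(genes, function(g) g$name %||% NA_character_, character(1))
  hit <- which(!is.na(aliases) & aliases == id)
  if (length(hit) == 1L) return(genes[[hit]])
  stop("gene not found: ", id, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stopin_gene <- function(x, ...) {
  cat("<stopin_gene> ", x$gene_id,
      if (!is.na(x$name)) paste0(" (", x$name, ")"), " [", x$chrom, x$strand,
      "], ", length(x$isoforms), " isoform(s)\n", sep = "")
  for (nm in names(x$isoforms)) {
    iv <- x$isoforms[[nm]]
    cat("  ", nm, ": ", nrow(iv), " CDS segment(s), spliced length ",
        sum(iv$end - iv$start), " nt\n", sep = "")
  }
  invisible(x)
}

#' Spliced CDS sequence and coordinate map of one isoform
#'
#' The returned sequence is the concatenation of the isoform's CDS slices in
#' transcription order, reverse-complemented for minus-strand genes. The
#' coordinate map is bijective over CDS bases: `genomic_pos[i]` is the
#' 0-based plus-strand coordinate underlying spliced-CDS base `i` (1-based
#' index into the string).
#'
#' @param gene A `stopin_gene`.
#' @param isoform_id Isoform identifier.
#' @param genome A `stopin_genome`.
#' @return List with `seq`, `genomic_pos`, `chrom`, `strand`.
#' @export
spliced_cds <- function(gene, isoform_id, genome) {
  stopifnot(inherits(gene, "stopin_gene"))
  if (!isoform_id %in% names(gene$isoforms)) {
    stop("unknown isoform '", isoform_id, "' for gene ", gene$gene_id,
         call. = FALSE)
  }
  iv <- gene$isoforms[[isoform_id]]
  pieces <- character(nrow(iv))
  pos <- vector("list", nrow(iv))
  for (i in seq_len(nrow(iv))) {
    pieces[i] <- genome_seq(genome, gene$chrom, iv$start[i], iv$end[i],
                            gene$strand)
    p <- seq.int(iv$start[i], iv$end[i] - 1L)
    if (gene$strand == "-") p <- rev(p)
    pos[[i]] <- p
  }
  list(seq = paste(pieces, collapse = ""),
       genomic_pos = as.integer(unlist(pos, use.names = FALSE)),
       chrom = gene$chrom, strand = gene$strand)
}

# CDS offset (0-based, in transcription order) of an insertion point given as
# a plus-strand between-bases coordinate. Counts the CDS bases transcribed
# before the cut.
#' @keywords internal
#' @noRd
cds_offset_of_cut <- function(cds_map, cut, strand) {
  if (strand == "+") sum(cds_map$genomic_pos < cut)
  else sum(cds_map$genomic_pos >= cut)
}

# TRUE if a between-bases plus-strand coordinate lies strictly inside any CDS
# interval of the isoform.
#' @keywords internal
#' @noRd
cut_in_cds <- function(gene, isoform_id, cut) {
  iv <- gene$isoforms[[isoform_id]]
  any(iv$start < cut & cut < iv$end)
}

#' Write gene models as GFF3 text
#'
#' Inverse of [load_annotation()] for the CDS-only models this package uses:
#' emits gene, mRNA and paired exon/CDS rows with 1-based inclusive
#' coordinates.
#'
#' @param genes List of `stopin_gene` objects.
#' @param path Output file; if `NULL` the lines are only returned.
#' @return Invisibly, the GFF3 lines.
#' @export
write_gff3 <- function(genes, path = NULL) {
  lines <- "##gff-version 3"
  for (g in genes) {
    all_iv <- do.call(rbind, g$isoforms)
    g_start <- min(all_iv$start) + 1L
    g_end <- max(all_iv$end)
    attr_name <- if (!is.na(g$name)) paste0(";Name=", g$name) else ""
    lines <- c(lines, paste(g$chrom, "stopin", "gene", g_start, g_end, ".",
                            g$strand, ".",
                            paste0("ID=", g$gene_id, attr_name), sep = "\t"))
    for (iso in names(g$isoforms)) {
      iv <- g$isoforms[[iso]]
      lines <- c(lines, paste(g$chrom, "stopin", "mRNA",
                              min(iv$start) + 1L, max(iv$end), ".", g$strand,
                              ".", paste0("ID=", iso, ";Parent=", g$gene_id),
                              sep = "\t"))
      ivo <- iv[order(iv$start), , drop = FALSE]
      for (k in seq_len(nrow(ivo))) {
        for (ty in c("exon", "CDS")) {
          lines <- c(lines, paste(g$chrom, "stopin", ty, ivo$start[k] + 1L,
                                  ivo$end[k], ".", g$strand,
                                  if (ty == "CDS") "0" else ".",
                                  paste0("ID=", iso, ":", ty, k,
                                         ";Parent=", iso), sep = "\t"))
        }
      }
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
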