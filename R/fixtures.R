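#' Specify a synthetic fixture gene
#'
#' Describes one gene for [make_fixture()]: chromosome strand, exon lengths,
#' optional multi-isoform structure (isoforms as subsets of exon indices),
#' and guide sites to plant. Exon lengths should be multiples of 3 when
#' isoforms skip exons, so every isoform stays in frame.
#'
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"` (chromosome strand of the coding sequence).
#' @param exon_lens Integer vector of exon (CDS segment) lengths in nt.
#' @param intron_len Length of each intervening intron.
#' @param isoforms Named list of integer vectors of exon indices in
#'   transcription order; default a single isoform using every exon.
#'   Exon 1 of every isoform must be exon 1 of the gene (shared start).
#' @param guides List of guide placements; each a list with elements
#'   `protospacer` (20-nt string, or `NULL` for random), `pam_strand`
#'   (chromosome strand of the PAM), `exon` (exon index to plant in),
#'   `phase` (0/1/2 cut phase in the all-exon CDS, or `NULL`), `unique`
#'   (default `TRUE`: enforce a single genome-wide exact match).
#' @return A `fixture_gene` spec list.
#' @export
fixture_gene <- function(gene_id, strand = "+",
                         exon_lens = c(120L, 120L, 120L),
                         intron_len = 60L, isoforms = NULL,
                         guides = list()) {
  stopifnot(strand %in% c("+", "-"), all(exon_lens >= 3L), intron_len >= 10L)
  if (is.null(isoforms)) {
    isoforms <- stats::setNames(list(seq_along(exon_lens)),
                                paste0(gene_id, ".t1"))
  }
  for (ex in isoforms) {
    stopifnot(all(ex %in% seq_along(exon_lens)), !is.unsorted(ex))
  }
  guides <- lapply(guides, function(g) {
    g$pam_strand <- g$pam_strand %||% "+"
    g$exon <- as.integer(g$exon %||% 1L)
    g$unique <- g$unique %||% TRUE
    stopifnot(g$pam_strand %in% c("+", "-"),
              g$exon %in% seq_along(exon_lens))
    g
  })
  structure(list(gene_id = gene_id, strand = strand,
                 exon_lens = as.integer(exon_lens),
                 intron_len = as.integer(intron_len),
                 isoforms = isoforms, guides = guides),
            class = "fixture_gene")
}

#' Generate a deterministic synthetic genome, annotation and guide manifest
#'
#' Builds a toy chromosome carrying the specified genes: stop-free random
#' coding sequence (ATG-initiated, stop-terminated when the CDS length is a
#' multiple of 3) split into exons by random introns, flanked by random
#' intergenic sequence, with the requested guide sites written into the
#' requested exons at the requested cut phases. Planted guides are the
#' ground truth for oracle tests: the manifest records each guide's
#' protospacer, PAM, strand, plus-strand span, cut coordinate, CDS offset,
#' phase and isoform coverage. Rejection sampling regenerates the random
#' sequence until (a) no isoform's spliced CDS has an internal in-frame
#' stop codon and (b) every uniqueness-requested guide has exactly one
#' genome-wide exact match. Identical seed and spec give byte-identical
#' output.
#'
#' @param genes List of [fixture_gene()] specs.
#' @param seed Integer RNG seed.
#' @param chrom Chromosome name.
#' @param intergenic Intergenic/flank length between and around genes.
#' @param max_tries Rejection-sampling cap before a spec error.
#' @return A `stopin_fixture`: `$genome`, `$genes` (named `stopin_gene`
#'   list), `$manifest` (data.frame), `$seed`.
#' @export
make_fixture <- function(genes, seed = 1L, chrom = "chrI",
                         intergenic = 400L, max_tries = 200L) {
  stopifnot(length(genes) >= 1L,
            all(vapply(genes, inherits, logical(1), "fixture_gene")))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  for (try in seq_len(max_tries)) {
    built <- try_build_fixture(genes, chrom, intergenic)
    if (!is.null(built)) {
      built$seed <- seed
      class(built) <- "stopin_fixture"
      return(built)
    }
  }
  stop("fixture spec infeasible: could not satisfy stop-free CDS and ",
       "guide-uniqueness constraints in ", max_tries, " attempts",
       call. = FALSE)
}

#' @keywords internal
#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.32, 0.18, 0.18, 0.32)), collapse = "")
}

#' @keywords internal
#' @noRd
random_nonstop_codons <- function(n) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  pool <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# One attempt at building the fixture; NULL signals rejection.
#' @keywords internal
#' @noRd
try_build_fixture <- function(genes, chrom, intergenic) {
  gene_builds <- lapply(genes, build_fixture_gene)
  # chromosome assembly
  pieces <- character(0)
  offset <- 0L
  manifest <- list()
  gene_models <- list()
  for (gb in gene_builds) {
    pieces <- c(pieces, random_dna(intergenic))
    offset <- offset + intergenic
    span <- gb$span_seq
    span_len <- nchar(span)
    spec <- gb$spec
    plus_span <- if (spec$strand == "+") span else reverse_complement(span)
    pieces <- c(pieces, plus_span)
    gstart <- offset
    offset <- offset + span_len

    to_plus_range <- function(lo, hi) {   # half-open sense-span offsets
      if (spec$strand == "+") c(gstart + lo, gstart + hi)
      else c(gstart + span_len - hi, gstart + span_len - lo)
    }
    isoforms <- lapply(spec$isoforms, function(ex_idx) {
      iv <- do.call(rbind, lapply(ex_idx, function(k) {
        r <- to_plus_range(gb$exon_span[k, "start"], gb$exon_span[k, "end"])
        data.frame(start = r[1L], end = r[2L])
      }))
      rownames(iv) <- NULL
      iv
    })
    gm <- new_gene_model(spec$gene_id, name = spec$gene_id, chrom = chrom,
                         strand = spec$strand, isoforms = isoforms)
    gene_models[[spec$gene_id]] <- gm

    for (pg in gb$planted) {
      sp <- to_plus_range(pg$span_start, pg$span_start + 23L)
      cut_plus <- if (spec$strand == "+") gstart + pg$cut_sense
                  else gstart + span_len - pg$cut_sense
      cov <- names(gm$isoforms)[vapply(names(gm$isoforms), function(id)
        cut_in_cds(gm, id, cut_plus), logical(1))]
      manifest[[length(manifest) + 1L]] <- data.frame(
        gene_id = spec$gene_id, protospacer = pg$protospacer, pam = pg$pam,
        pam_strand = pg$pam_strand, chrom = chrom,
        start = sp[1L], end = sp[2L], cut = cut_plus,
        cds_offset = pg$cds_offset, phase = pg$cds_offset %% 3L,
        exon = pg$exon, unique = pg$unique,
        isoform_coverage = paste(cov, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  pieces <- c(pieces, random_dna(intergenic))
  genome <- genome_from_sequences(stats::setNames(
    paste(pieces, collapse = ""), chrom))
  manifest <- do.call(rbind, manifest)

  # rejection check 1: every isoform's spliced CDS internally stop-free
  for (gm in gene_models) {
    for (iso in names(gm$isoforms)) {
      cds <- spliced_cds(gm, iso, genome)$seq
      offs <- stop_offsets_by_frame(cds)[["1"]]
      n_codon <- nchar(cds) %/% 3L
      internal <- offs[offs < (n_codon - 1L) * 3L]
      if (length(internal)) return(NULL)
    }
  }
  # rejection check 2: planted-guide uniqueness
  if (!is.null(manifest)) {
    for (i in seq_len(nrow(manifest))) {
      if (!manifest$unique[i]) next
      if (genome_match_count(paste0(manifest$protospacer[i],
                                    manifest$pam[i]), genome) != 1L) {
        return(NULL)
      }
    }
  }
  list(genome = genome, genes = gene_models, manifest = manifest)
}

# Build one gene's sense-strand span with guides planted in the CDS.
#' @keywords internal
#' @noRd
build_fixture_gene <- function(spec) {
  total <- sum(spec$exon_lens)
  cds <- if (total %% 3L == 0L) {
    paste0("ATG", random_nonstop_codons(total %/% 3L - 2L), "TAA")
  } else {
    substr(random_nonstop_codons(total %/% 3L + 1L), 1L, total)
  }
  ends <- cumsum(spec$exon_lens)
  starts <- c(0L, ends[-length(ends)])  # CDS offsets per exon, half-open

  planted <- list()
  for (g in spec$guides) {
    sense_oriented <- g$pam_strand == spec$strand
    cut_rel <- if (sense_oriented) 17L else 6L
    a <- starts[g$exon]; b <- ends[g$exon]
    if (b - a < 23L) {
      stop("exon ", g$exon, " of ", spec$gene_id,
           " too short to hold a 23-nt guide window", call. = FALSE)
    }
    p <- a + (b - 23L - a) %/% 2L
    if (!is.null(g$phase)) {
      shift <- (as.integer(g$phase) - (p + cut_rel)) %% 3L
      p <- p + shift
      if (p > b - 23L) p <- p - 3L
      if (p < a) {
        stop("exon ", g$exon, " of ", spec$gene_id,
             " cannot host requested phase", call. = FALSE)
      }
    }
    proto <- g$protospacer %||%
      paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
            collapse = "")
    pam <- paste0(sample(c("A", "C", "G", "T"), 1L), "GG")
    site_sense <- if (sense_oriented) paste0(proto, pam)
                  else reverse_complement(paste0(proto, pam))
    cds <- paste0(substr(cds, 1L, p), site_sense,
                  substr(cds, p + 24L, nchar(cds)))
    planted[[length(planted) + 1L]] <- list(
      protospacer = toupper(proto), pam = pam, pam_strand = g$pam_strand,
      cds_plant = p, cds_offset = p + cut_rel, exon = g$exon,
      unique = g$unique)
  }

  # interleave exons with introns; record span offsets of each exon
  span <- ""
  exon_span <- matrix(0L, nrow = length(spec$exon_lens), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
  for (k in seq_along(spec$exon_lens)) {
    if (k > 1L) span <- paste0(span, random_dna(spec$intron_len))
    exon_span[k, "start"] <- nchar(span)
    span <- paste0(span, substr(cds, starts[k] + 1L, ends[k]))
    exon_span[k, "end"] <- nchar(span)
  }
  # translate planted CDS offsets into sense-span offsets
  for (i in seq_along(planted)) {
    pg <- planted[[i]]
    k <- pg$exon
    planted[[i]]$span_start <- exon_span[k, "start"] +
      (pg$cds_plant - starts[k])
    planted[[i]]$cut_sense <- exon_span[k, "start"] +
      (pg$cds_offset - starts[k])
  }
  list(spec = spec, span_seq = span, exon_span = exon_span,
       planted = planted)
}

#' @export
print.stopin_fixture <- function(x, ...) {
  cat("<stopin_fixture> seed ", x$seed, ", ",
      sum(chrom_lengths(x$genome)), " bp, ", length(x$genes),
      " gene(s), ", if (is.null(x$manifest)) 0L else nrow(x$manifest),
      " planted guide(s)\n", sep = "")
  invisible(x)
}

#' Write a fixture to FASTA + GFF3 + JSON manifest
#'
#' @param fixture A `stopin_fixture`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "stopin_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  man <- file.path(dir, "manifest.json")
  write_genome_fasta(fixture$genome, fa)
  write_gff3(fixture$genes, gff)
  jsonlite::write_json(fixture$manifest, man, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, gff3 = gff, manifest = man))
}

#' Matched wild-type / knocked-in genome pair from a fixture
#'
#' Convenience wrapper for genotyping and verification work: takes one
#' planted guide, designs the knock-in oligo, applies simulated HDR, and
#' returns the pair of genomes with the plan.
#'
#' @param fixture A `stopin_fixture` with at least one planted guide.
#' @param guide_row Row index into `fixture$manifest`.
#' @param arm_len Homology-arm length.
#' @return List with `wt`, `ki` (genomes), `plan` (`edit_plan`), `oligo`,
#'   `guide` (manifest row as list), `gene`.
#' @export
make_edited_pair <- function(fixture, guide_row = 1L, arm_len = 35L) {
  stopifnot(inherits(fixture, "stopin_fixture"),
            !is.null(fixture$manifest),
            guide_row %in% seq_len(nrow(fixture$manifest)))
  g <- as.list(fixture$manifest[guide_row, ])
  gene <- fixture$genes[[g$gene_id]]
  oligo <- design_knockin_oligo(g, gene, fixture$genome, arm_len = arm_len)
  plan <- edit_plan(g, oligo, gene, fixture$genome)
  ki <- simulate_hdr(fixture$genome, plan)
  list(wt = fixture$genome, ki = ki, plan = plan, oligo = oligo,
       guide = g, gene = gene)
}
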