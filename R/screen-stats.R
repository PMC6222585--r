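#' Read a knock-in screen results table
#'
#' TSV schema: `gene`, `alleles`, `guide`, `n_genotyped` (number of F1
#' plates genotyped), `n_ki` (number with a successful cassette insertion),
#' `lethal` (logical: allele could not be homozygosed), `marker`
#' (co-conversion marker, `dpy-10` or `unc-58`). Counts are the primary
#' data; percentages are always recomputed with [ki_percent()].
#'
#' @param path TSV file; default is the packaged 22-experiment screen table
#'   (21 genes, `clik-3` targeted twice).
#' @return A `screen_table` data.frame.
#' @export
read_screen_table <- function(path = system.file("extdata",
                                                 "screen_results.tsv",
                                                 package = "stopin")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "guide", "n_genotyped", "n_ki", "lethal", "marker")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("screen table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$lethal <- as.logical(df$lethal)
  if (any(df$n_ki > df$n_genotyped)) {
    stop("n_ki exceeds n_genotyped in row(s): ",
         paste(which(df$n_ki > df$n_genotyped), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$n_genotyped < 0) || any(df$n_ki < 0)) {
    stop("negative counts in screen table", call. = FALSE)
  }
  class(df) <- c("screen_table", "data.frame")
  df
}

#' Knock-in percentage of a screen record
#'
#' `100 * n_ki / n_genotyped`, rounded half away from zero to an integer —
#' the convention that reproduces every printed per-gene percentage of the
#' packaged table (e.g. 21/24 = 87.5 reports as 88, 15/24 = 62.5 as 63).
#' Note base R's `round()` rounds half to even and would give 88 -> 88 but
#' 62.5 -> 62, so the rule is implemented explicitly.
#'
#' @param n_genotyped,n_ki Non-negative integer vectors (recycled).
#' @return Integer percent vector.
#' @export
ki_percent <- function(n_genotyped, n_ki) {
  if (any(n_genotyped <= 0)) {
    stop("knock-in rate undefined when n_genotyped is 0", call. = FALSE)
  }
  if (any(n_ki > n_genotyped) || any(n_ki < 0)) {
    stop("n_ki must lie in [0, n_genotyped]", call. = FALSE)
  }
  x <- 100 * n_ki / n_genotyped
  as.integer(floor(x + 0.5))
}

#' Pooled knock-in efficiency over screen records
#'
#' Sums the counts first, then applies the [ki_percent()] arithmetic to the
#' sums (not the mean of per-row percentages). On the packaged table this
#' reproduces the headline pooled efficiency: 322/694 = 46%.
#'
#' @param records A `screen_table` (or compatible data.frame).
#' @param subset Optional logical vector selecting rows.
#' @return List with `percent`, `n_total`, `n_ki`.
#' @export
pooled_efficiency <- function(records, subset = NULL) {
  if (!is.null(subset)) records <- records[subset, , drop = FALSE]
  if (nrow(records) == 0L) {
    stop("no records selected", call. = FALSE)
  }
  n_total <- sum(records$n_genotyped)
  n_ki <- sum(records$n_ki)
  list(percent = ki_percent(n_total, n_ki), n_total = n_total, n_ki = n_ki)
}

#' Chi-square comparison of knock-in efficiency between two groups
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 table of (KI, non-KI) x group, as used to compare putative-lethal
#' against non-lethal target genes. Margins reconcile with
#' [pooled_efficiency()] of the two groups.
#'
#' @param records A `screen_table`.
#' @param group Logical vector (or name of a logical column, default
#'   `"lethal"`) splitting the records into groups A (`TRUE`) and B.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A `group_comparison`: `table` (2x2 counts), `statistic`,
#'   `p_value`, `df`, `rates` (per-group percent via [ki_percent()]),
#'   `n` (per-group totals), `expected`, `warning` (set when an expected
#'   cell is below 1).
#' @export
compare_groups <- function(records, group = "lethal", correct = FALSE) {
  if (is.character(group) && length(group) == 1L) {
    group <- as.logical(records[[group]])
  }
  stopifnot(length(group) == nrow(records))
  a <- records[group, , drop = FALSE]
  b <- records[!group, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pa <- pooled_efficiency(a); pb <- pooled_efficiency(b)
  tab <- matrix(c(pa$n_ki, pa$n_total - pa$n_ki,
                  pb$n_ki, pb$n_total - pb$n_ki),
                nrow = 2L, byrow = TRUE,
                dimnames = list(group = c("A", "B"),
                                outcome = c("KI", "no_KI")))
  ht <- stats::chisq.test(tab, correct = correct)
  warn <- if (any(ht$expected < 1)) {
    "an expected cell count is below 1; consider an exact test"
  } else NULL
  if (!is.null(warn)) warning(warn, call. = FALSE)
  structure(list(
    table = tab,
    statistic = unname(ht$statistic),
    p_value = unname(ht$p.value),
    df = unname(ht$parameter),
    expected = ht$expected,
    rates = c(A = pa$percent, B = pb$percent),
    n = c(A = pa$n_total, B = pb$n_total),
    correct = correct,
    warning = warn
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> Pearson chi-square",
      if (x$correct) "(Yates-corrected)", "\n")
  print(x$table)
  cat(sprintf("rates: A %d%% (n = %d) vs B %d%% (n = %d)\n",
              x$rates[["A"]], x$n[["A"]], x$rates[["B"]], x$n[["B"]]))
  cat(sprintf("X-squared = %.4f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$warning)) cat("note:", x$warning, "\n")
  invisible(x)
}

#' Ribonucleoprotein injection-mix recipe
#'
#' The published injection recipe, parameterized by co-conversion marker.
#' Final concentrations: 3.4 ug/uL Cas9 protein, 45.9 uM annealed guide RNA
#' mixture, 0.51 uM repair oligo for the gene of interest, and 0.25 uM
#' (`dpy-10`) or 0.51 uM (`unc-58`) repair oligo for the marker. The
#' annealing mix is 2.5 uL of 100 uM tracrRNA with 0.5 uL marker crRNA +
#' 2.0 uL target crRNA (`dpy-10`) or 1.0 uL marker + 1.5 uL target
#' (`unc-58`).
#'
#' @param marker `"dpy-10"` or `"unc-58"`.
#' @return An `injection_mix`: `$final` data.frame of final concentrations
#'   and `$annealing` data.frame of crRNA/tracrRNA volumes.
#' @export
injection_mix <- function(marker = c("dpy-10", "unc-58")) {
  marker <- tryCatch(match.arg(marker), error = function(e)
    stop("unknown marker; supported markers: dpy-10, unc-58", call. = FALSE))
  marker_oligo <- if (marker == "dpy-10") 0.25 else 0.51
  final <- data.frame(
    component = c("Cas9 protein", "annealed guide RNA mixture",
                  "repair oligo (target gene)",
                  paste0("repair oligo (", marker, ")")),
    concentration = c(3.4, 45.9, 0.51, marker_oligo),
    unit = c("ug/uL", "uM", "uM", "uM"),
    stringsAsFactors = FALSE)
  vols <- if (marker == "dpy-10") c(2.5, 0.5, 2.0) else c(2.5, 1.0, 1.5)
  annealing <- data.frame(
    component = c("tracrRNA (100 uM)",
                  paste0(marker, " crRNA (100 uM)"),
                  "target-gene crRNA (100 uM)"),
    volume_uL = vols,
    stringsAsFactors = FALSE)
  structure(list(marker = marker, final = final, annealing = annealing),
            class = "injection_mix")
}

#' @export
print.injection_mix <- function(x, ...) {
  cat("<injection_mix> co-conversion marker:", x$marker, "\n")
  cat("final concentrations:\n"); print.data.frame(x$final)
  cat("crRNA/tracrRNA annealing mix:\n"); print.data.frame(x$annealing)
  cat("note: efficiencies for lethal targets may be underestimates;",
      "F1 animals carrying two loss-of-function alleles are not recovered.\n")
  invisible(x)
}
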