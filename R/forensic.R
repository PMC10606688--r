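# Forensic summary statistics. All haplotype-level statistics are functions
# of the multiplicity spectrum alone: with N men and a spectrum counting
# how many distinct haplotypes occur k times,
#   HMP = sum_i p_i^2 = sum_k spectrum[k] * (k/N)^2   (match probability)
#   HD  = N (1 - HMP) / (N - 1)                       (haplotype diversity)
#   DC  = M / N                                       (discrimination capacity)
# and the per-locus analogue of HD over allele frequencies a_i is the gene
# diversity GD = N (1 - sum a_i^2) / (N - 1).

check_spectrum <- function(spectrum, N) {
  k <- as.integer(names(spectrum))
  if (length(spectrum) == 0L || any(is.na(k)) || any(k < 1L))
    stop("spectrum must be a named vector keyed by multiplicity", call. = FALSE)
  if (!is.null(N) && sum(k * spectrum) != N)
    stop("inconsistent spectrum: sum(k * spectrum[k]) = ", sum(k * spectrum),
         " but N = ", N, call. = FALSE)
  k
}

#' Haplotype match probability
#'
#' The probability that two men drawn at random from the sample share a
#' haplotype: `HMP = sum(p_i^2)` over haplotype frequencies `p_i = k/N`.
#'
#' @param spectrum named vector: multiplicity k -> number of distinct
#'   haplotypes seen k times (as from [multiplicity_spectrum()]).
#' @param N sample size (default: implied by the spectrum).
#' @return HMP, a fraction in (0, 1].
#' @export
match_probability <- function(spectrum, N = NULL) {
  k <- check_spectrum(spectrum, N)
  if (is.null(N)) N <- sum(k * spectrum)
  sum(spectrum * (k / N)^2)
}

#' Haplotype diversity
#'
#' Sample-corrected probability that two random men differ in haplotype:
#' `HD = N (1 - sum p_i^2) / (N - 1)`. Equals 1 exactly when every
#' haplotype is unique and 0 when the sample is monomorphic.
#'
#' @inheritParams match_probability
#' @return HD in \[0, 1\] (full precision; round to 6 decimals for
#'   reporting).
#' @examples
#' haplotype_diversity(c("1" = 877, "2" = 15, "3" = 1))
#' @export
haplotype_diversity <- function(spectrum, N = NULL) {
  k <- check_spectrum(spectrum, N)
  if (is.null(N)) N <- sum(k * spectrum)
  if (N < 2L) stop("haplotype diversity undefined for N < 2", call. = FALSE)
  N * (1 - match_probability(spectrum, N)) / (N - 1)
}

#' Discrimination capacity
#'
#' `DC = M/N`: the fraction of the sample carrying a distinct haplotype.
#'
#' @param M number of distinct haplotypes.
#' @param N sample size.
#' @return DC in (0, 1].
#' @export
discrimination_capacity <- function(M, N) {
  if (M < 1L || M > N)
    stop("inconsistent counts: need 1 <= M <= N, got M = ", M, ", N = ", N,
         call. = FALSE)
  M / N
}

#' Gene diversity from allele category counts
#'
#' Per-locus analogue of haplotype diversity:
#' `GD = N (1 - sum a_i^2) / (N - 1)` over allele frequencies `a_i`.
#' For the multi-copy locus DYS385a/b each distinct sorted allele pair (or
#' larger multiset) is one category, so the locus gets a single GD value.
#'
#' @param counts named or unnamed vector of per-category counts.
#' @param N sample size (default `sum(counts)`).
#' @return GD in \[0, 1\].
#' @examples
#' gene_diversity(c(a = 7, b = 3))  # 10 * (1 - 0.58) / 9
#' @export
gene_diversity <- function(counts, N = sum(counts)) {
  if (N < 2L) stop("gene diversity undefined for N < 2", call. = FALSE)
  if (sum(counts) != N)
    stop("counts must sum to N", call. = FALSE)
  N * (1 - sum((counts / N)^2)) / (N - 1)
}

#' Per-locus allele frequency table and gene diversity
#'
#' Tabulates canonical allele categories at one locus. By default each
#' distinct cell (for DYS385a/b, the sorted allele pair/multiset) is one
#' category; `mode = "allele"` instead pools every individual allele of
#' multi-allele cells.
#'
#' @param d a `ystr_dataset`.
#' @param locus locus name.
#' @param mode `"cell"` (one category per canonical cell, default) or
#'   `"allele"` (pool all alleles).
#' @return list with fields `locus`, `counts` (named), `frequencies`,
#'   `N`, `GD`.
#' @export
locus_frequency_table <- function(d, locus, mode = c("cell", "allele")) {
  mode <- match.arg(mode)
  if (!locus %in% d$loci) stop("unknown locus: ", locus, call. = FALSE)
  cells <- d$cells[, locus]
  cells <- cells[!is.na(cells)]
  if (length(cells) < 2L)
    stop("gene diversity undefined for N < 2", call. = FALSE)
  cats <- if (mode == "cell") cells
          else unlist(strsplit(cells, "-", fixed = TRUE))
  tab <- table(cats)
  counts <- setNames(as.integer(tab), names(tab))
  N <- sum(counts)
  list(locus = locus, counts = counts, frequencies = counts / N, N = N,
       GD = gene_diversity(counts, N))
}

#' Gene diversity table across all loci
#'
#' @param d a `ystr_dataset`.
#' @param loci loci to summarise (default all).
#' @return data.frame with columns `locus`, `n_categories`, `N`, `GD`.
#' @export
locus_gd_table <- function(d, loci = d$loci) {
  rows <- lapply(loci, function(l) {
    ft <- locus_frequency_table(d, l)
    data.frame(locus = l, n_categories = length(ft$counts), N = ft$N,
               GD = ft$GD, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multi-panel forensic summary
#'
#' Computes, for each panel, the sample size after exclusions, the number
#' of distinct haplotypes M, HD, HMP and DC — the standard survey summary
#' table. Across the nested built-in chain HD and DC are non-decreasing and
#' HMP non-increasing in panel size.
#'
#' @param d a `ystr_dataset` complete for the largest requested panel.
#' @param panels named list of locus vectors (default: the five built-ins)
#'   or character vector of registered panel names.
#' @return data.frame with one row per panel: `panel`, `N`, `M`, `HD`,
#'   `HMP`, `DC`, plus attribute `"spectra"` (named list of spectra).
#' @export
panel_summary_table <- function(d, panels = ystr_panels()) {
  if (is.character(panels))
    panels <- setNames(lapply(panels, panel_loci), panels)
  spectra <- lapply(panels, function(loci) multiplicity_spectrum(d, loci))
  rows <- Map(function(nm, sp) {
    k <- as.integer(names(sp))
    N <- sum(k * sp); M <- sum(sp)
    data.frame(panel = nm, N = N, M = M,
               HD = haplotype_diversity(sp, N),
               HMP = match_probability(sp, N),
               DC = discrimination_capacity(M, N),
               stringsAsFactors = FALSE)
  }, names(panels), spectra)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spectra") <- spectra
  out
}

#' Spectrum as percentages of distinct haplotypes
#'
#' Expresses each multiplicity class as a percentage of the M distinct
#' haplotypes, rounded to 2 decimals (e.g. 877 of 893 unique = 98.21).
#'
#' @param spectrum named multiplicity spectrum.
#' @return named numeric vector of percentages.
#' @export
spectrum_percentages <- function(spectrum) {
  check_spectrum(spectrum, NULL)
  M <- sum(spectrum)
  round(100 * spectrum / M, 2)
}

#' Render the forensic summary for display
#'
#' HD and DC rounded to 6 decimals; HMP in scientific notation with 3
#' significant digits. Internal values stay at full precision.
#'
#' @param summary data.frame from [panel_summary_table()].
#' @return data.frame of formatted character columns.
#' @export
format_panel_summary <- function(summary) {
  data.frame(panel = summary$panel, N = summary$N, M = summary$M,
             HD = sprintf("%.6f", summary$HD),
             HMP = sprintf("%.2e", summary$HMP),
             DC = sprintf("%.6f", summary$DC),
             stringsAsFactors = FALSE)
}
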