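# Pairwise Rst by two-level AMOVA on squared repeat-count differences.
# With x_il the repeat count of individual i at locus l,
#   d(i,j)     = sum_l (x_il - x_jl)^2
#   SSD_total  = (1/2N)  sum_i sum_j d(i,j)
#   SSD_within = sum_p (1/2n_p) sum_{i,j in p} d(i,j)
#   SSD_among  = SSD_total - SSD_within
#   MSD_among  = SSD_among / (P - 1),  MSD_within = SSD_within / (N - P)
#   n_c        = (N - sum_p n_p^2 / N) / (P - 1)
#   sigma2_a   = (MSD_among - MSD_within) / n_c
#   Rst        = sigma2_a / (sigma2_a + MSD_within)
# Rst may be slightly negative when populations are effectively identical;
# raw values are reported, and clamped to 0 only for embedding/tree use.

#' Numeric repeat-count matrix for distance computations
#'
#' Extracts single numeric repeat values at the chosen loci. Multi-allele
#' cells (the duplicated locus DYS385a/b, copy-number variants) and missing
#' calls have no single value and yield `NA`; [pairwise_rst()] drops such
#' individuals with a logged count. Microvariants enter either at numeric
#' face value (13.1, default) or rounded to integer repeats.
#'
#' @param d a `ystr_dataset`.
#' @param loci loci to extract (default all).
#' @param microvariants `"value"` (13.1 stays 13.1) or `"round"` (13.1
#'   becomes 13).
#' @return numeric matrix (individuals x loci).
#' @export
repeat_matrix <- function(d, loci = d$loci,
                          microvariants = c("value", "round")) {
  microvariants <- match.arg(microvariants)
  absent <- setdiff(loci, d$loci)
  if (length(absent))
    stop("dataset lacks loci: ", paste(absent, collapse = ", "), call. = FALSE)
  cells <- d$cells[, loci, drop = FALSE]
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                  dimnames = list(d$samples, loci)))
  vals[!is.na(cells) & cell_size(cells) > 1L] <- NA  # CNV / multi-copy
  if (microvariants == "round") vals <- floor(vals)
  vals
}

# Core variance-component decomposition given a full squared-distance
# matrix D (N x N) and an integer population index per individual.
amova_components <- function(D, pop) {
  N <- nrow(D)
  sizes <- tabulate(pop)
  sizes <- sizes[sizes > 0L]
  P <- length(sizes)
  ssd_total <- sum(D) / (2 * N)
  ssd_within <- 0
  for (g in unique(pop)) {
    idx <- which(pop == g)
    ssd_within <- ssd_within + sum(D[idx, idx]) / (2 * length(idx))
  }
  msd_among <- (ssd_total - ssd_within) / (P - 1)
  msd_within <- ssd_within / (N - P)
  n_c <- (N - sum(sizes^2) / N) / (P - 1)
  sigma2_a <- (msd_among - msd_within) / n_c
  denom <- sigma2_a + msd_within
  rst <- if (denom == 0) 0 else sigma2_a / denom
  list(rst = rst, sigma2_a = sigma2_a, msd_within = msd_within,
       ssd_total = ssd_total, ssd_within = ssd_within, n_c = n_c)
}

# Pool two datasets into (values matrix, population factor), applying the
# locus restrictions and CNV/missing exclusions.
pool_pair <- function(a, b, loci, microvariants = "value", quiet = FALSE) {
  if ("DYS385ab" %in% loci) {
    if (!quiet) message("multi-copy locus DYS385ab excluded from Rst")
    loci <- setdiff(loci, "DYS385ab")
  }
  if (length(loci) == 0L) stop("empty locus list for Rst", call. = FALSE)
  va <- repeat_matrix(a, loci, microvariants)
  vb <- repeat_matrix(b, loci, microvariants)
  ka <- rowSums(is.na(va)) == 0L
  kb <- rowSums(is.na(vb)) == 0L
  dropped <- sum(!ka) + sum(!kb)
  if (dropped > 0L && !quiet)
    message(dropped, " individual(s) dropped from Rst (missing or ",
            "copy-number-variant calls)")
  if (sum(ka) < 2L || sum(kb) < 2L)
    stop("fewer than 2 usable individuals in a population after filtering",
         call. = FALSE)
  list(values = rbind(va[ka, , drop = FALSE], vb[kb, , drop = FALSE]),
       pop = rep(1:2, c(sum(ka), sum(kb))), loci = loci)
}

#' Pairwise Rst between two populations
#'
#' Two-level AMOVA over squared repeat-count differences summed across
#' loci. The multi-copy locus DYS385a/b and individuals with missing or
#' copy-number-variant calls at any chosen locus are excluded (logged).
#'
#' @param a,b `ystr_dataset` objects, one population each.
#' @param loci loci to use (default: intersection of the two locus sets).
#' @param microvariants see [repeat_matrix()].
#' @param quiet suppress exclusion messages.
#' @return list of class `rst_result`: `pop_a`, `pop_b`, `rst` (raw; may be
#'   slightly negative), `n_a`, `n_b`, `loci_used`, and the AMOVA
#'   components.
#' @export
pairwise_rst <- function(a, b, loci = intersect(a$loci, b$loci),
                         microvariants = c("value", "round"),
                         quiet = FALSE) {
  microvariants <- match.arg(microvariants)
  pooled <- pool_pair(a, b, loci, microvariants, quiet)
  D <- as.matrix(stats::dist(pooled$values))^2
  comp <- amova_components(D, pooled$pop)
  structure(
    list(pop_a = a$name, pop_b = b$name, rst = comp$rst,
         n_a = sum(pooled$pop == 1L), n_b = sum(pooled$pop == 2L),
         loci_used = pooled$loci, components = comp),
    class = "rst_result"
  )
}

#' @export
print.rst_result <- function(x, ...) {
  cat("Rst(", x$pop_a, ", ", x$pop_b, ") = ", signif(x$rst, 4),
      "  [n = ", x$n_a, " + ", x$n_b, ", ", length(x$loci_used),
      " loci]\n", sep = "")
  if (!is.null(x$p_value))
    cat("permutation p = ", signif(x$p_value, 4), " (B = ", x$permutations,
        ")\n", sep = "")
  invisible(x)
}

#' Permutation significance test for Rst
#'
#' Permutes population labels across the pooled individuals, holding group
#' sizes fixed, and reports `p = (#{Rst* >= Rst_obs} + 1) / (B + 1)`.
#' Reproducible given `seed`.
#'
#' @inheritParams pairwise_rst
#' @param B number of permutations (>= 100).
#' @param seed integer RNG seed (mandatory).
#' @return an `rst_result` with `p_value` and `permutations` fields added.
#' @export
rst_permutation_test <- function(a, b, loci = intersect(a$loci, b$loci),
                                 B = 9999L, seed,
                                 microvariants = c("value", "round"),
                                 quiet = FALSE) {
  if (missing(seed)) stop("seed is required for the permutation test",
                          call. = FALSE)
  if (B < 100L) stop("need at least 100 permutations", call. = FALSE)
  microvariants <- match.arg(microvariants)
  pooled <- pool_pair(a, b, loci, microvariants, quiet)
  D <- as.matrix(stats::dist(pooled$values))^2
  obs <- amova_components(D, pooled$pop)
  N <- nrow(D)
  n1 <- sum(pooled$pop == 1L)
  set.seed(seed)
  perm <- vapply(seq_len(B), function(i) {
    idx <- sample.int(N)
    p <- integer(N); p[idx[seq_len(n1)]] <- 1L; p[idx[-seq_len(n1)]] <- 2L
    amova_components(D, p)$rst
  }, numeric(1L))
  pval <- (sum(perm >= obs$rst - 1e-12) + 1) / (B + 1)
  structure(
    list(pop_a = a$name, pop_b = b$name, rst = obs$rst,
         p_value = pval, permutations = as.integer(B),
         n_a = n1, n_b = N - n1, loci_used = pooled$loci, components = obs),
    class = "rst_result"
  )
}

#' Bonferroni-corrected per-test significance level
#'
#' For k pairwise comparisons at family-wise level `alpha`, the per-test
#' threshold is `alpha / k`, reported to 2 significant figures (e.g. 66
#' pairs of 12 populations at alpha = 0.05 gives 0.00076).
#'
#' @param alpha family-wise level in (0, 1).
#' @param k number of comparisons (>= 1).
#' @return per-test alpha.
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(k) || k < 1) stop("k must be a positive count", call. = FALSE)
  signif(alpha / k, 2)
}

#' Pairwise Rst matrix over several populations
#'
#' Computes all pairwise Rst values (and permutation p-values when `B > 0`)
#' among a list of populations.
#'
#' @param datasets list of `ystr_dataset` objects with distinct names.
#' @param loci loci to use (default: intersection across datasets).
#' @param B permutations per pair (0 disables the tests).
#' @param seed integer RNG seed (required when `B > 0`).
#' @param microvariants see [repeat_matrix()].
#' @param quiet suppress exclusion messages.
#' @return list of class `rst_matrix`: `labels`, `rst` (symmetric matrix,
#'   zero diagonal, raw values), `p_values` (or `NULL`), `clamped`
#'   (negatives set to 0, for MDS/tree use).
#' @export
rst_matrix <- function(datasets, loci = NULL, B = 0L, seed = NULL,
                       microvariants = c("value", "round"), quiet = FALSE) {
  if (length(datasets) < 2L) stop("need at least 2 populations", call. = FALSE)
  microvariants <- match.arg(microvariants)
  labels <- vapply(datasets, function(d) d$name, character(1L))
  if (anyDuplicated(labels)) stop("population names must be distinct",
                                  call. = FALSE)
  if (is.null(loci))
    loci <- Reduce(intersect, lapply(datasets, function(d) d$loci))
  L <- length(datasets)
  rst <- matrix(0, L, L, dimnames = list(labels, labels))
  pmat <- if (B > 0L) rst + 1 else NULL
  if (B > 0L && is.null(seed))
    stop("seed is required when permutations are requested", call. = FALSE)
  pair_id <- 0L
  for (i in seq_len(L - 1L)) for (j in seq(i + 1L, L)) {
    pair_id <- pair_id + 1L
    res <- if (B > 0L)
      rst_permutation_test(datasets[[i]], datasets[[j]], loci, B = B,
                           seed = seed + pair_id, microvariants = microvariants,
                           quiet = quiet)
    else pairwise_rst(datasets[[i]], datasets[[j]], loci,
                      microvariants = microvariants, quiet = quiet)
    rst[i, j] <- rst[j, i] <- res$rst
    if (B > 0L) pmat[i, j] <- pmat[j, i] <- res$p_value
  }
  if (!is.null(pmat)) diag(pmat) <- NA_real_
  structure(
    list(labels = labels, rst = rst, p_values = pmat,
         clamped = pmax(rst, 0), loci_used = setdiff(loci, "DYS385ab"),
         permutations = B),
    class = "rst_matrix"
  )
}

#' @export
print.rst_matrix <- function(x, ...) {
  cat("Pairwise Rst over", length(x$labels), "populations",
      if (x$permutations > 0L) paste0("(", x$permutations,
                                      " permutations per pair)"), "\n")
  print(round(x$rst, 4))
  invisible(x)
}

#' Write an Rst (or any labelled symmetric) matrix as TSV
#'
#' @param m numeric matrix with dimnames, or an `rst_matrix` (writes the
#'   raw Rst values).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "rst_matrix")) m <- m$rst
  df <- data.frame(label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled symmetric matrix from TSV
#'
#' Inverse of [write_matrix_tsv()]; validates symmetry.
#'
#' @param path TSV with a `label` column followed by one column per label.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"label" %in% names(df) || ncol(df) != nrow(df) + 1L)
    stop("malformed matrix file: ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  storage.mode(m) <- "double"
  if (any(is.na(m)) || max(abs(m - t(m))) > 1e-8)
    stop("matrix in ", path, " is not symmetric", call. = FALSE)
  m
}
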