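# Synthetic haplotype data. Two generators:
#  * exact-spectrum constructors that build a dataset whose multiplicity
#    spectrum under one panel (or a nested chain of panels) equals a given
#    spectrum exactly -- used to reproduce published count spectra when the
#    per-sample appendix data are not available;
#  * a stepwise-mutation-model (SMM) simulator of structured populations:
#    founder haplotypes drawn uniformly from per-locus ranges, lineages
#    accumulating symmetric single-step mutations (+/-1 repeat with
#    probability mu per locus per generation), populations splitting a
#    configurable number of generations ago.

# ---- exact-spectrum constructors -------------------------------------------

# per-locus category label lists used to enumerate distinct haplotypes
locus_categories <- function(loci, ranges = allele_ranges()) {
  lapply(loci, function(l) {
    r <- ranges[[l]]
    if (is.null(r)) r <- c(7L, 25L)
    vals <- as.character(seq(r[1L], r[2L]))
    if (l == "DYS385ab") {
      pairs <- expand.grid(a = seq(r[1L], r[2L]), b = seq(r[1L], r[2L]))
      pairs <- pairs[pairs$a <= pairs$b, ]
      vals <- paste(pairs$a, pairs$b, sep = "-")
    }
    vals
  })
}

# m-th (0-based) distinct combination over the category lists, mixed radix
combo_cells <- function(m, cats) {
  vapply(cats, function(cv) {
    d <- m %% length(cv)
    m <<- m %/% length(cv)
    cv[d + 1L]
  }, character(1L))
}

#' Build a dataset with an exact multiplicity spectrum
#'
#' Constructs `M = sum(spectrum)` distinct haplotypes over the panel's loci
#' (distinct by construction: distinct allele combinations) and replicates
#' each according to its multiplicity, so that
#' `multiplicity_spectrum(result, panel)` equals `spectrum` exactly.
#'
#' @param spectrum named vector: multiplicity k -> number of distinct
#'   haplotypes to occur exactly k times.
#' @param panel panel name or locus vector.
#' @param seed integer seed (controls the row order only).
#' @param name,population dataset labels.
#' @return a `ystr_dataset` with `N = sum(k * spectrum[k])` individuals.
#' @examples
#' d <- dataset_from_spectrum(c("1" = 3, "2" = 1), "Minimal", seed = 1)
#' multiplicity_spectrum(d, "Minimal")
#' @export
dataset_from_spectrum <- function(spectrum, panel, seed, name = "synthetic",
                                  population = name) {
  k <- check_spectrum(spectrum, NULL)
  loci <- panel_loci(panel)
  cats <- locus_categories(loci)
  M <- sum(spectrum)
  if (M > prod(vapply(cats, length, numeric(1L))))
    stop("spectrum needs ", M, " distinct haplotypes but the allele space ",
         "is smaller", call. = FALSE)
  class_cells <- t(vapply(seq_len(M) - 1L, combo_cells, character(length(loci)),
                          cats = cats))
  colnames(class_cells) <- loci
  sizes <- rep(k, spectrum)
  cells <- class_cells[rep(seq_len(M), sizes), , drop = FALSE]
  set.seed(seed)
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
  ystr_dataset(cells, populations = population, name = name)
}

# Exact refinement of a partition: assign child parts (largest first) to
# the parent slot with the largest remaining capacity. Returns a list of
# child-size vectors, one per parent part (parents taken in decreasing
# order). Errors if no exact assignment is found this way.
solve_refinement <- function(parent_sizes, child_sizes) {
  if (sum(parent_sizes) != sum(child_sizes))
    stop("spectra are inconsistent: totals differ", call. = FALSE)
  ord <- order(parent_sizes, decreasing = TRUE)
  cap <- parent_sizes[ord]
  assign <- vector("list", length(cap))
  for (c0 in sort(child_sizes, decreasing = TRUE)) {
    i <- which.max(cap)
    if (cap[i] < c0)
      stop("no consistent refinement of the nested spectra found",
           call. = FALSE)
    cap[i] <- cap[i] - c0
    assign[[i]] <- c(assign[[i]], c0)
  }
  out <- vector("list", length(cap))
  out[ord] <- assign
  out
}

#' Build one dataset matching spectra under a chain of nested panels
#'
#' Given multiplicity spectra for each panel of a nested chain (e.g. the
#' five built-ins), constructs a single dataset whose spectrum under every
#' panel equals the corresponding input exactly. Haplotype classes are
#' refined level by level: loci added by each panel split the classes of
#' the previous level into the required child multiplicities. Errors if the
#' spectra admit no consistent refinement.
#'
#' @param spectra named list of spectra, one per panel, in chain order.
#' @param panels named list of locus vectors, nested, same order/names as
#'   `spectra` (default: the built-in chain).
#' @param seed integer seed (controls the row order only).
#' @param name,population dataset labels.
#' @return a `ystr_dataset` over the largest panel's loci.
#' @export
dataset_from_spectra <- function(spectra, panels = ystr_panels(), seed,
                                 name = "synthetic", population = name) {
  stopifnot(length(spectra) == length(panels), length(panels) >= 1L)
  for (i in seq_along(panels)[-1L])
    if (!all(panels[[i - 1L]] %in% panels[[i]]))
      stop("panels must be nested in order", call. = FALSE)
  sizes_of <- function(sp) {
    k <- check_spectrum(sp, NULL)
    sort(rep(k, sp), decreasing = TRUE)
  }
  ranges <- allele_ranges()

  loci1 <- panels[[1L]]
  sizes <- sizes_of(spectra[[1L]])
  cats <- locus_categories(loci1, ranges)
  if (length(sizes) > prod(vapply(cats, length, numeric(1L))))
    stop("first-level spectrum exceeds the allele space", call. = FALSE)
  class_cells <- t(vapply(seq_along(sizes) - 1L, combo_cells,
                          character(length(loci1)), cats = cats))
  colnames(class_cells) <- loci1

  for (lev in seq_along(panels)[-1L]) {
    added <- setdiff(panels[[lev]], panels[[lev - 1L]])
    child_sizes <- sizes_of(spectra[[lev]])
    split_plan <- solve_refinement(sizes, child_sizes)
    enc_locus <- added[1L]
    base <- (ranges[[enc_locus]] %||% c(10L, 25L))[1L]
    base_cells <- vapply(added, function(l)
      as.character((ranges[[l]] %||% c(10L, 25L))[1L]), character(1L))
    n_children <- lengths(split_plan)
    if (max(n_children) > diff(ranges[[enc_locus]] %||% c(10L, 25L)) + 1L)
      stop("refinement needs more values at ", enc_locus,
           " than its allele range provides", call. = FALSE)
    parent_rows <- rep(seq_len(nrow(class_cells)), n_children)
    new_cells <- class_cells[parent_rows, , drop = FALSE]
    add_block <- matrix(rep(base_cells, each = length(parent_rows)),
                        ncol = length(added),
                        dimnames = list(NULL, added))
    child_rank <- unlist(lapply(n_children, seq_len))
    add_block[, enc_locus] <- as.character(base + child_rank - 1L)
    class_cells <- cbind(new_cells, add_block)[, panels[[lev]], drop = FALSE]
    sizes <- unlist(split_plan)
  }

  cells <- class_cells[rep(seq_len(nrow(class_cells)), sizes), , drop = FALSE]
  set.seed(seed)
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
  ystr_dataset(cells, populations = population, name = name)
}

#' Published-spectra fixture: a Luzhou-like 910-man dataset
#'
#' A synthetic stand-in for a published 910-male, 24-locus Han (Luzhou)
#' sample whose per-sample haplotypes are not publicly deposited. The
#' construction matches the published multiplicity spectra under all five
#' built-in panels exactly (877 unique haplotypes, 15 doubletons, one
#' tripleton under the full panel), and injects the reported allele
#' anomalies: DYS458 microvariants 13.1, 14.1, 15.1 and five DYS385a/b
#' copy-number variants (one tri-allelic, three tetra-allelic, one
#' penta-allelic). Only the counting structure is realistic; allele values
#' and their frequencies are conventional, not the study's.
#'
#' @param seed integer seed (row order); regeneration with the same seed is
#'   byte-identical.
#' @return a `ystr_dataset` with N = 910 over the Microreader24Y loci.
#' @export
luzhou_like_fixture <- function(seed = 1L) {
  spectra <- luzhou_spectra()
  d <- dataset_from_spectra(spectra, ystr_panels(), seed = seed,
                            name = "LuzhouHan_synthetic")
  # rows unique under the Minimal panel stay unique under every finer
  # panel, so editing loci there cannot change any spectrum
  keys <- haplotype_keys(d, panel_loci("Minimal"))
  singletons <- which(keys %in% names(which(table(keys) == 1L)))
  stopifnot(length(singletons) >= 8L)
  mv_rows <- singletons[1:3]
  d$cells[mv_rows, "DYS458"] <- c("13.1", "14.1", "15.1")
  cnv_rows <- singletons[4:8]
  d$cells[cnv_rows, "DYS385ab"] <- c("11-14-15",
                                     "10-13-14-15", "11-13-14-16",
                                     "12-14-15-17", "10-12-13-15-16")
  d
}

#' Published multiplicity spectra of the Luzhou Han survey panels
#'
#' The "count of observed haplotypes" spectra of a published 910-male
#' Luzhou Han sample under the five nested panels, shipped as package data.
#'
#' @return named list of spectra in chain order (Minimal ...
#'   Microreader24Y).
#' @export
luzhou_spectra <- function() {
  path <- system.file("extdata", "luzhou_spectra.tsv", package = "ystrkit",
                      mustWork = TRUE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  out <- lapply(names(df)[-1L], function(col) {
    keep <- df[[col]] > 0L
    setNames(as.integer(df[[col]][keep]), df$multiplicity[keep])
  })
  setNames(out, names(df)[-1L])
}

# ---- stepwise-mutation-model simulator -------------------------------------

#' Configuration for the SMM population simulator
#'
#' @param n_individuals males sampled per population.
#' @param loci locus names (default: the Microreader24Y panel).
#' @param mu mutation probability per locus per generation (scalar or one
#'   value per locus). A mutation changes the repeat count by +1 or -1 with
#'   equal probability (single-step model).
#' @param n_founders number of founder lineages in the ancestral pool.
#' @param generations total generations simulated.
#' @param divergence_generations generations since the populations split
#'   (<= `generations`); 0 means panmixia.
#' @param n_populations number of populations to emit.
#' @param microvariant_rate per-individual probability of a DYS458
#'   microvariant call (partial repeat ".1").
#' @param cnv_rate per-individual probability of a DYS385a/b copy-number
#'   variant (a third allele).
#' @param ranges named list of founder allele ranges (default
#'   [allele_ranges()]).
#' @param seed integer RNG seed (mandatory).
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 100L,
                              loci = ystr_panels()[["Microreader24Y"]],
                              mu = 0.002, n_founders = 20L,
                              generations = 500L,
                              divergence_generations = 100L,
                              n_populations = 2L,
                              microvariant_rate = 0, cnv_rate = 0,
                              ranges = allele_ranges(), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (length(mu) == 1L) mu <- rep(mu, length(loci))
  if (length(mu) != length(loci))
    stop("mu must be scalar or one value per locus", call. = FALSE)
  rates <- c(mu, microvariant_rate, cnv_rate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (generations < 0L || divergence_generations < 0L ||
      divergence_generations > generations)
    stop("need 0 <= divergence_generations <= generations", call. = FALSE)
  if (n_individuals < 2L || n_founders < 1L || n_populations < 1L)
    stop("invalid population sizes", call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals), loci = loci,
                 mu = mu, n_founders = as.integer(n_founders),
                 generations = as.integer(generations),
                 divergence_generations = as.integer(divergence_generations),
                 n_populations = as.integer(n_populations),
                 microvariant_rate = microvariant_rate, cnv_rate = cnv_rate,
                 ranges = ranges, seed = as.integer(seed)),
            class = "simulation_config")
}

# net repeat displacement of n lineages after t generations at rate mu:
# mutation count ~ Binomial(t, mu), each step +1/-1 with prob 1/2
smm_displacement <- function(n, t, mu) {
  if (t == 0L || mu == 0) return(integer(n))
  k <- rbinom(n, t, mu)
  2L * rbinom(n, k, 0.5) - k
}

#' Simulate structured Y-STR populations under the stepwise mutation model
#'
#' Founder haplotypes are drawn uniformly from the per-locus ranges and
#' evolve by symmetric single-step mutation along a two-level star
#' genealogy. All populations share the ancestral founder pool, which
#' evolves for `generations - divergence_generations` generations. At the
#' split each population acquires a private trunk lineage that accumulates
#' `divergence_generations` of mutations shared by all its members -- this
#' is what makes between-population variance, and hence Rst, grow with
#' divergence time. Each sampled man then inherits a founder state drawn
#' from the pool plus `divergence_generations` of private mutations (a
#' star genealogy within the population, so within-population pairwise
#' variance grows at 2 mu per generation of divergence). The duplicated
#' locus DYS385a/b is simulated as two copies reported as one unordered
#' pair; microvariant and copy-number-variant calls are injected at the
#' configured rates.
#'
#' @param cfg a [simulation_config()].
#' @return list of `ystr_dataset` objects named `pop1`, `pop2`, ...
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  # internal columns: DYS385ab contributes two independently evolving copies
  cols <- unlist(lapply(cfg$loci, function(l)
    if (l == "DYS385ab") c("DYS385ab#1", "DYS385ab#2") else l))
  col_locus <- sub("#.*$", "", cols)
  mu <- cfg$mu[match(col_locus, cfg$loci)]
  founders <- vapply(col_locus, function(l) {
    r <- cfg$ranges[[l]] %||% c(7L, 25L)
    sample(seq(r[1L], r[2L]), cfg$n_founders, replace = TRUE)
  }, integer(cfg$n_founders))
  founders <- matrix(founders, nrow = cfg$n_founders)
  t_shared <- cfg$generations - cfg$divergence_generations
  split_state <- founders
  for (j in seq_along(cols))
    split_state[, j] <- split_state[, j] +
      smm_displacement(cfg$n_founders, t_shared, mu[j])
  out <- vector("list", cfg$n_populations)
  for (p in seq_len(cfg$n_populations)) {
    # population trunk: post-split mutations shared by every member
    trunk <- vapply(seq_along(cols), function(j)
      smm_displacement(1L, cfg$divergence_generations, mu[j]), integer(1L))
    idx <- sample.int(cfg$n_founders, cfg$n_individuals, replace = TRUE)
    X <- split_state[idx, , drop = FALSE]
    for (j in seq_along(cols))
      X[, j] <- X[, j] + trunk[j] +
        smm_displacement(cfg$n_individuals, cfg$divergence_generations, mu[j])
    X[X < 1L] <- 1L
    lab <- matrix(as.character(X), nrow = nrow(X))
    # microvariants at DYS458: partial-repeat labels such as "14.1"
    if ("DYS458" %in% col_locus && cfg$microvariant_rate > 0) {
      j <- which(col_locus == "DYS458")[1L]
      hit <- runif(cfg$n_individuals) < cfg$microvariant_rate
      lab[hit, j] <- paste0(lab[hit, j], ".1")
    }
    cells <- matrix(NA_character_, cfg$n_individuals, length(cfg$loci),
                    dimnames = list(NULL, cfg$loci))
    for (l in cfg$loci) {
      jj <- which(col_locus == l)
      cells[, l] <- if (length(jj) == 1L) lab[, jj]
                    else paste(lab[, jj[1L]], lab[, jj[2L]], sep = "-")
    }
    # copy-number variants at DYS385a/b: an extra allele in the cell
    if ("DYS385ab" %in% cfg$loci && cfg$cnv_rate > 0) {
      hit <- runif(cfg$n_individuals) < cfg$cnv_rate
      extra <- X[hit, which(col_locus == "DYS385ab")[1L]] + 1L
      cells[hit, "DYS385ab"] <- paste(cells[hit, "DYS385ab"], extra, sep = "-")
    }
    nm <- paste0("pop", p)
    out[[p]] <- ystr_dataset(cells, populations = nm, name = nm)
  }
  setNames(out, vapply(out, function(d) d$name, character(1L)))
}
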