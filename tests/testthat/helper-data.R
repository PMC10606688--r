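# Small in-code data builders shared across tests.

# dataset of n individuals with uniformly random integer alleles
random_dataset <- function(n, loci = ystr_panels()[["Microreader24Y"]],
                           seed = 1, spread = 3L, name = "rand",
                           population = name) {
  set.seed(seed)
  ranges <- allele_ranges()
  cells <- vapply(loci, function(l) {
    r <- ranges[[l]]
    v <- as.character(sample(seq(r[1L], r[1L] + spread), n, replace = TRUE))
    if (l == "DYS385ab")
      v <- paste(v, sample(seq(r[1L], r[1L] + spread), n, replace = TRUE),
                 sep = "-")
    v
  }, character(n))
  cells <- matrix(cells, nrow = n, dimnames = list(NULL, loci))
  ystr_dataset(cells, populations = population, name = name)
}

# single-locus dataset from a plain numeric vector of repeat counts
one_locus_pop <- function(x, name, locus = "DYS391") {
  cells <- matrix(as.character(x), ncol = 1L, dimnames = list(NULL, locus))
  ystr_dataset(cells, populations = name, name = name)
}

# random multiplicity spectrum (for property tests over spectra)
random_spectrum <- function(seed) {
  set.seed(seed)
  ks <- sort(sample(1:12, sample(2:6, 1)))
  setNames(sample(1:40, length(ks), replace = TRUE), ks)
}
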