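test_that("spectrum constructor is exact for feasible spectra", {
  # trivial shapes
  d1 <- dataset_from_spectrum(c("1" = 3), "Minimal", seed = 2)
  expect_identical(multiplicity_spectrum(d1, "Minimal"), c("1" = 3L))
  d2 <- dataset_from_spectrum(c("2" = 1), "Minimal", seed = 2)
  expect_identical(multiplicity_spectrum(d2, "Minimal"), c("2" = 1L))
  expect_identical(haplotype_diversity(multiplicity_spectrum(d2)), 0)
  # random spectra: exact reproduction, not approximate
  for (s in 1:10) {
    sp <- random_spectrum(600 + s)
    sp_int <- setNames(as.integer(sp), names(sp))
    d <- dataset_from_spectrum(sp, "Yfiler", seed = s)
    expect_identical(multiplicity_spectrum(d, "Yfiler"), sp_int)
  }
  # infeasible: more distinct haplotypes than the allele space allows
  expect_error(dataset_from_spectrum(c("1" = 1e6), c("DYS437"), seed = 1),
               "allele space")
})

test_that("nested-spectra constructor solves the published chain exactly", {
  spectra <- luzhou_spectra()
  d <- dataset_from_spectra(spectra, ystr_panels(), seed = 4)
  for (p in names(spectra)) {
    got <- multiplicity_spectrum(d, p)
    expect_identical(got, spectra[[p]][names(got)], label = p)
  }
  # inconsistent totals are refused rather than approximated
  bad <- spectra
  bad$Minimal["1"] <- bad$Minimal["1"] + 1L
  expect_error(dataset_from_spectra(bad, ystr_panels(), seed = 1),
               "inconsistent|refinement")
})

test_that("the Luzhou-like fixture has the published anomalies and is
           reproducible", {
  d <- luzhou_like_fixture(seed = 9)
  expect_identical(n_samples(d), 910L)
  expect_length(d$loci, 23L)
  # microvariant alleles at DYS458, including 13.1
  expect_true(all(c("13.1", "14.1", "15.1") %in% d$cells[, "DYS458"]))
  # five DYS385a/b copy-number variants with 3-5 alleles
  sz <- cell_size(d$cells[, "DYS385ab"])
  expect_identical(sort(sz[sz > 2]), c(3L, 4L, 4L, 4L, 5L))
  # regeneration with the same seed is byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write_haplotype_table(luzhou_like_fixture(seed = 9), f1)
  write_haplotype_table(luzhou_like_fixture(seed = 9), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("SMM simulator honours its degenerate limits", {
  # mu = 0: every individual equals its founder haplotype
  cfg0 <- simulation_config(n_individuals = 20, loci = c("DYS391", "DYS392"),
                            mu = 0, n_founders = 1, generations = 100,
                            divergence_generations = 50, seed = 3)
  pops <- simulate_populations(cfg0)
  for (d in pops)
    expect_identical(length(unique(haplotype_keys(d))), 1L)
  # config validation
  expect_error(simulation_config(mu = 2, seed = 1), "rates")
  expect_error(simulation_config(generations = 10,
                                 divergence_generations = 20, seed = 1),
               "divergence")
  expect_error(simulation_config(), "seed")
})

test_that("SMM variance grows like 2 * mu * t between independent lineages", {
  # one founder, full divergence: E[(x_i - x_j)^2] = 2 * mu * t,
  # averaged over replicate simulations to tame Monte-Carlo noise
  mu <- 0.01; t <- 400
  v <- mean(vapply(1:6, function(s) {
    cfg <- simulation_config(n_individuals = 400, loci = "DYS391", mu = mu,
                             n_founders = 1, generations = t,
                             divergence_generations = t, n_populations = 1,
                             seed = s)
    x <- repeat_matrix(simulate_populations(cfg)[[1]])[, 1]
    mean(outer(x, x, "-")^2)
  }, numeric(1)))
  expect_equal(v, 2 * mu * t, tolerance = 0.1)
})

test_that("divergence time drives Rst: zero at panmixia, monotone after", {
  loci <- ystr_panels()[["PowerPlexY23"]]
  null_rst <- vapply(1:12, function(s) {
    cfg <- simulation_config(n_individuals = 40, loci = loci, mu = 0.002,
                             generations = 400, divergence_generations = 0,
                             seed = 800 + s)
    pops <- simulate_populations(cfg)
    suppressMessages(pairwise_rst(pops[[1]], pops[[2]]))$rst
  }, numeric(1))
  expect_lt(abs(median(null_rst)), 0.02)  # Monte-Carlo band around 0
  med_rst <- vapply(c(50L, 500L), function(dv) {
    r <- vapply(1:10, function(s) {
      cfg <- simulation_config(n_individuals = 60, loci = loci, mu = 0.002,
                               generations = 600,
                               divergence_generations = dv, seed = 900 + s)
      pops <- simulate_populations(cfg)
      suppressMessages(pairwise_rst(pops[[1]], pops[[2]]))$rst
    }, numeric(1))
    median(r)
  }, numeric(1))
  expect_gt(med_rst[2], med_rst[1])
})

test_that("simulated anomalies appear at the configured rates", {
  cfg <- simulation_config(n_individuals = 300, loci = c("DYS458", "DYS385ab"),
                           mu = 0.001, generations = 100,
                           divergence_generations = 0, n_populations = 1,
                           microvariant_rate = 0.1, cnv_rate = 0.1, seed = 21)
  d <- simulate_populations(cfg)[[1]]
  expect_gt(sum(grepl("\\.1", d$cells[, "DYS458"])), 0)
  expect_gt(sum(cell_size(d$cells[, "DYS385ab"]) > 2), 0)
})
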