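# Published reference values for the 910-man Luzhou Han survey: the five
# panel spectra with their printed HD/HMP/DC rows.
luzhou_expected <- data.frame(
  panel = c("Minimal", "PowerPlexY12", "Yfiler", "PowerPlexY23",
            "Microreader24Y"),
  M = c(701L, 768L, 857L, 888L, 893L),
  HD = c(0.998784, 0.999429, 0.999823, 0.999944, 0.999956),
  HMP_mantissa = c(2.31, 1.67, 1.28, 1.15, 1.14),  # x 10^-3
  DC = c(0.770330, 0.843956, 0.941758, 0.975824, 0.981319)
)

test_that("haplotype diversity reproduces the published panel values", {
  sp24 <- c("1" = 877, "2" = 15, "3" = 1)
  expect_equal(round(haplotype_diversity(sp24, 910), 6), 0.999956)
  spmin <- c("1" = 590, "2" = 74, "3" = 16, "4" = 9, "5" = 3, "6" = 5,
             "9" = 2, "10" = 1, "15" = 1)
  expect_equal(round(haplotype_diversity(spmin, 910), 6), 0.998784)
  # boundary cases: all unique is exactly 1, monomorphic exactly 0
  expect_identical(haplotype_diversity(c("1" = 57)), 1)
  expect_identical(haplotype_diversity(c("57" = 1)), 0)
  expect_error(haplotype_diversity(c("1" = 1)), "N < 2")
  expect_error(haplotype_diversity(spmin, 900), "inconsistent")
})

test_that("match probability is the exact pair-match fraction", {
  spmin <- c("1" = 590, "2" = 74, "3" = 16, "4" = 9, "5" = 3, "6" = 5,
             "9" = 2, "10" = 1, "15" = 1)
  expect_equal(match_probability(spmin, 910), 1916 / 828100)
  expect_equal(match_probability(c("1" = 20)), 1 / 20)
  expect_identical(match_probability(c("20" = 1)), 1)
  # brute-force oracle: exhaustive pairwise match count / N^2, N <= 30
  for (s in 1:10) {
    sp <- random_spectrum(400 + s)
    keys <- rep(seq_along(rep(as.integer(names(sp)), sp)),
                rep(as.integer(names(sp)), sp))
    if (length(keys) > 30) keys <- keys[1:30]
    sp_trunc <- table(table(keys))
    sp_trunc <- setNames(as.integer(sp_trunc), names(sp_trunc))
    expect_equal(match_probability(sp_trunc), hmp_oracle(keys),
                 tolerance = 1e-12)
  }
})

test_that("discrimination capacity and its bounds", {
  expect_equal(round(discrimination_capacity(893, 910), 6), 0.981319)
  expect_equal(round(discrimination_capacity(701, 910), 6), 0.770330)
  expect_identical(discrimination_capacity(44, 44), 1)
  expect_error(discrimination_capacity(45, 44), "inconsistent")
})

test_that("HD and HMP satisfy HD = N(1 - HMP)/(N - 1) on random spectra", {
  for (s in 1:50) {
    sp <- random_spectrum(s)
    N <- sum(as.integer(names(sp)) * sp)
    hd <- haplotype_diversity(sp, N)
    hmp <- match_probability(sp, N)
    expect_equal(hd, N * (1 - hmp) / (N - 1), tolerance = 1e-12)
    expect_true(hd >= 0 && hd <= 1 && hmp > 0 && hmp <= 1)
  }
})

test_that("gene diversity over allele categories", {
  expect_equal(gene_diversity(c(a = 7, b = 3)), 10 * (1 - 0.58) / 9)
  # two distinct sorted pairs, N = 2
  expect_identical(gene_diversity(c("11-14" = 1, "12-13" = 1)), 1)
  expect_identical(gene_diversity(c(a = 12)), 0)
  expect_error(gene_diversity(c(a = 1)), "N < 2")
  # multi-copy cells form one category per sorted multiset, so DYS385a/b
  # gets a single GD value
  d <- ystr_dataset(matrix(c("11-14", "14-11", "12-13"), ncol = 1,
                           dimnames = list(NULL, "DYS385ab")))
  ft <- locus_frequency_table(d, "DYS385ab")
  expect_identical(ft$counts, c("11-14" = 2L, "12-13" = 1L))
  expect_equal(sum(ft$frequencies), 1, tolerance = 1e-12)
  expect_equal(ft$GD, gene_diversity(c(2, 1)))
  # optional pooled-allele mode
  fa <- locus_frequency_table(d, "DYS385ab", mode = "allele")
  expect_identical(sum(fa$counts), 6L)
})

test_that("panel summary reproduces per-statistic calls and statistics are
           label-invariant", {
  d <- random_dataset(30, seed = 9, spread = 1L)
  summ <- panel_summary_table(d, panels = "Yfiler")
  sp <- multiplicity_spectrum(d, "Yfiler")
  expect_equal(summ$HD, haplotype_diversity(sp))
  expect_equal(summ$HMP, match_probability(sp))
  expect_equal(summ$DC, sum(sp) / 30)
  # relabelling alleles consistently leaves every statistic unchanged
  d2 <- d
  d2$cells[, "DYS19"] <- as.character(
    as.integer(d2$cells[, "DYS19"]) + 5L)
  expect_equal(panel_summary_table(d2, panels = "Yfiler")[, -1],
               summ[, -1], ignore_attr = TRUE)
})

test_that("forensic parameters are monotone under panel nesting", {
  for (s in 1:15) {
    d <- random_dataset(35, seed = 200 + s, spread = 1L)
    summ <- panel_summary_table(d)
    expect_true(all(diff(summ$M) >= 0))
    expect_true(all(diff(summ$HD) >= -1e-12))
    expect_true(all(diff(summ$DC) >= 0))
    expect_true(all(diff(summ$HMP) <= 1e-12))
  }
})

test_that("spectrum percentages match the published unique/doubleton shares", {
  pct <- spectrum_percentages(c("1" = 877, "2" = 15, "3" = 1))
  expect_equal(unname(pct), c(98.21, 1.68, 0.11))
  expect_equal(unname(spectrum_percentages(c("1" = 12))), 100)
  expect_equal(unname(spectrum_percentages(c("2" = 5))), 100)
})

test_that("the exact-spectrum fixture reproduces the full published table", {
  d <- luzhou_like_fixture(seed = 1)
  summ <- panel_summary_table(d)
  expect_identical(summ$panel, luzhou_expected$panel)
  expect_identical(summ$M, luzhou_expected$M)
  expect_equal(round(summ$HD, 6), luzhou_expected$HD)
  expect_equal(round(summ$HMP * 1e3, 2), luzhou_expected$HMP_mantissa)
  expect_equal(round(summ$DC, 6), luzhou_expected$DC)
  # distinct-haplotype gain from the Minimal to the full panel
  gain <- (summ$M[5] - summ$M[1]) / summ$M[1]
  expect_equal(round(100 * gain, 2), 27.39)
})
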