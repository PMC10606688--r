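Package: ystrkit
Title: Forensic Y-STR Haplotype Diversity and Population Structure Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "ystrkit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for forensic analysis of Y-chromosomal short tandem
    repeat (Y-STR) haplotype data. Reads tab-separated haplotype tables in
    the allele notation used by forensic reference databases (microvariant
    alleles such as "13.1", multi-copy cells such as "11-14"), projects
    haplotypes onto standard marker panels (Minimal haplotype through
    Microreader 24Y), and computes the standard forensic summary
    statistics: haplotype diversity, haplotype match probability,
    discrimination capacity, and per-locus gene diversity. Population
    structure is assessed with pairwise Rst distances estimated by a
    two-level analysis of molecular variance (AMOVA) over squared
    repeat-count differences, with permutation significance tests and
    Bonferroni correction, classical multidimensional scaling, and
    neighbor-joining trees with Newick export. A synthetic-data module
    provides an exact multiplicity-spectrum dataset constructor and a
    stepwise-mutation-model simulator of diverging male populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
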