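---
title: "Y-STR forensic statistics and population structure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Y-STR forensic statistics and population structure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrkit)
```

## The data and its conventions

A Y-STR haplotype table has one row per male individual and one column per
locus. Alleles are named by repeat count, with microvariants written as
`repeats.extra_bases` (`13.1` = 13 repeats plus one base; the partial part
is always 1–3 bases, shorter than a repeat unit). The duplicated locus
DYS385a/b is typed as one unordered allele pair in a single cell
(`11-14`); copy-number variants produce cells with three or more alleles
at DYS385a/b or more than one allele at a normally single-copy locus.

Two conventions matter throughout:

* **Identity is defined on labels, not numbers.** `13.1` is a category,
  not the quantity 13.1; haplotype counting and gene diversity treat each
  distinct sorted allele multiset as one category. Numeric values are used
  only where a distance requires them (Rst), where the face value 13.1 is
  the default and rounding to 13 is available
  (`repeat_matrix(..., microvariants = "round")`) because reference
  databases do not document their convention.
* **Cells are canonical.** Multi-allele cells are sorted ascending, so
  `14-11` and `11-14` are the same call, and a write/read round trip
  preserves haplotype keys exactly.

DYS389II is used exactly as reported by the typing kit, without
subtracting DYS389I: published summary tables are kit outputs, and the
statistics here must reproduce them.

The five built-in panels (Minimal, PowerPlex Y12, Yfiler, PowerPlex Y23,
Microreader 24Y) form a nested chain and are shipped as a JSON registry;
the memberships are the standard forensic definitions, and an alternative
registry file can be loaded (`ystr_panels(file)`). Individuals missing any
locus of a panel are excluded from that panel's statistics with a logged
count.

## Forensic summary statistics

Every haplotype-level statistic is a function of the multiplicity spectrum
alone — the map $k \mapsto$ number of distinct haplotypes observed exactly
$k$ times in $N$ men:

$$\mathrm{HMP} = \sum_i p_i^2, \qquad
  \mathrm{HD} = \frac{N\,(1 - \sum_i p_i^2)}{N-1}, \qquad
  \mathrm{DC} = \frac{M}{N},$$

with $p_i = k_i/N$ and $M$ the number of distinct haplotypes. HD is the
sample-corrected probability that two random men differ; it is exactly 1
when all haplotypes are unique and exactly 0 for a monomorphic sample. The
identity $\mathrm{HD} = N(1-\mathrm{HMP})/(N-1)$ holds to machine
precision and is enforced by a property test. Gene diversity
$\mathrm{GD} = N(1-\sum_i a_i^2)/(N-1)$ is the per-locus analogue over
allele-category frequencies; the $N/(N-1)$ correction is applied to GD
too, matching forensic reporting practice. For DYS385a/b the default
category is the sorted pair/multiset, which is what yields a single GD
value for the locus; a pooled per-allele mode exists but is off by
default.

Display rounding follows the field's tables: HD and DC to 6 decimals, HMP
in scientific notation with 3 significant digits, spectrum percentages to
2 decimals, Bonferroni thresholds to 2 significant figures. Internal
values are kept at full precision.

## Rst by two-level AMOVA

With $x_{il}$ the numeric repeat count of individual $i$ at locus $l$, the
inter-individual distance is $d(i,j) = \sum_l (x_{il}-x_{jl})^2$. The
analysis of molecular variance partitions the total sum of squared
deviations,

$$\mathrm{SSD_{total}} = \frac{1}{2N}\sum_i\sum_j d(i,j), \qquad
  \mathrm{SSD_{within}} = \sum_p \frac{1}{2n_p}\sum_{i,j \in p} d(i,j),$$

into within- and among-population components with degrees of freedom
$N-P$ and $P-1$. With
$n_c = (N - \sum_p n_p^2/N)/(P-1)$, the among-population variance
component is $\sigma^2_a = (\mathrm{MSD_{among}} -
\mathrm{MSD_{within}})/n_c$ and

$$R_{st} = \frac{\sigma^2_a}{\sigma^2_a + \mathrm{MSD_{within}}}.$$

$R_{st}$ may be slightly negative when populations are effectively
identical; tables report the raw value, and it is clamped to 0 only where
a non-negative distance is required (MDS, neighbor joining). The
implementation is checked against an independent brute-force transcription
of the formulas (explicit double loops) to $10^{-10}$ on random instances.

Loci entering Rst must contribute one number per man, so the multi-copy
locus DYS385a/b is excluded by default and individuals with missing or
copy-number-variant calls at any chosen locus are dropped (both logged).
An alternative (averaging the allele multiset) was considered and
rejected as the default: it manufactures intermediate values that no
chromosome carries, and reference-database practice is undocumented.

Significance uses a label permutation test holding group sizes fixed:
$p = (\#\{R_{st}^* \ge R_{st}\} + 1)/(B+1)$, default $B = 9999$, seed
mandatory. The test's type-I error at $\alpha = 0.05$ is verified to sit
inside the 95% binomial band over 200 null replicates. Family-wise
control over $k$ pairwise comparisons uses the Bonferroni threshold
$\alpha/k$ (66 pairs of 12 populations at $\alpha = 0.05$ gives 0.00076).

## Embedding and trees

**Classical MDS** double-centers the squared distances,
$B = -\tfrac12 J D^2 J$, eigendecomposes, and scales the top eigenvectors
by $\sqrt{\lambda}$. Non-positive eigenvalues contribute zero coordinates
(with a warning when the requested dimension exceeds the rank), and each
axis is oriented so its largest-magnitude coordinate is positive — a pure
sign convention that makes plots reproducible across platforms. Exact
Euclidean inputs are recovered to Procrustes residual $<10^{-8}$.

**Neighbor joining** follows the Q-criterion,
$Q(i,j) = (L-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, with the
standard limb-length formulas, negative limbs clamped to 0, and the final
three clusters joined by the three-point equations. Ties in $Q$ are broken
on the lexicographically smallest pair of representative leaf labels, and
children are ordered by representative label, so equivalent inputs
serialise to identical Newick strings. The output is an unrooted `phylo`
object ($L-2$ internal nodes); on additive matrices the generating
topology is recovered and path lengths reproduce the input to $10^{-9}$.
The Newick writer quotes labels containing metacharacters and emits
6-decimal branch lengths.

## The synthetic-data generators

Real per-sample haplotypes for the motivating 910-man survey are not
publicly deposited; two generators stand in.

**Exact-spectrum construction.** `dataset_from_spectrum()` enumerates
distinct haplotypes mixed-radix over per-locus allele ranges and
replicates each to its multiplicity, so the spectrum is matched exactly,
never approximately. `dataset_from_spectra()` extends this to a nested
panel chain: classes at each level are split by the loci the next panel
adds, with child multiplicities assigned greedily (largest child to the
largest remaining parent capacity) and an error — not an approximation —
when no exact refinement exists. The published five-panel chain is
solvable (no parent class splits into more than 3 children), which is why
a single 910-man fixture reproduces all five published summary columns at
once. `luzhou_like_fixture()` additionally injects the reported anomalies
(DYS458 microvariants 13.1/14.1/15.1; five DYS385a/b copy-number variants
of sizes 3–5) only into rows that are singletons under the smallest
panel, which provably cannot change any spectrum. The fixture is
regenerated at runtime (deterministic, byte-identical per seed) rather
than shipped as a file; only the 11-line printed-spectra table is
packaged. Allele *values* in these datasets are conventional range-based
labels: the counting structure is faithful, allele frequencies are not,
which is why per-locus GD values of the survey are not reproduced (they
require the unavailable per-sample data) while every spectrum-derived
statistic is exact.

**Stepwise-mutation-model simulator.** `simulate_populations()` evolves
integer repeat counts by the single-step model — mutation with probability
$\mu$ per locus per generation, $\pm 1$ repeat with equal probability —
consistent with the observation that Y-STR father–son mutations are
almost always single-repeat changes. The genealogy is a two-level star:
an ancestral founder pool (default 20 lineages, uniform founder alleles
within per-locus ranges) evolves for
`generations - divergence_generations`; at the split each population
gains a private trunk carrying `divergence_generations` of shared
mutations, and each sampled man adds the same span of private mutations.
Displacements are drawn in closed form ($2\,\mathrm{Bin}(k,\tfrac12)-k$
with $k \sim \mathrm{Bin}(t,\mu)$), which is distributionally identical
to the generation-by-generation walk. Consequences, all under test:
within-population pairwise variance grows at $2\mu t$; at zero divergence
the populations are exchangeable and Rst is centred on 0; median Rst
increases monotonically with divergence time. DYS385a/b is simulated as
two independently evolving copies reported as a sorted pair; microvariant
and CNV calls are injected at configurable per-individual rates
(default 0).

What the simulator does *not* emulate: coalescent genealogies (the star
approximation understates within-population haplotype correlation),
locus-specific mutation-rate spectra, multi-step mutations, and real
allele-frequency distributions. A green simulation-based test therefore
establishes correct behaviour of the estimators under a stylised but
well-specified data-generating process, not agreement with any particular
real population. Defaults — $\mu = 0.002$ per locus per generation (the
order of magnitude of common Y-STR rates), 100 men per population, 20
founders — were fixed once as field-plausible desk-scale values.

## Numerical and design choices

* Spectrum-consistency (`sum k·spectrum[k] = N`) is validated before any
  statistic; `N < 2` is an error, not NaN.
* Permutation p-values count ties as exceedances (with a $10^{-12}$
  absolute guard against float noise), keeping the test valid.
* When both AMOVA variance components are exactly zero (all haplotypes
  identical everywhere), Rst is defined as 0.
* The fixture generators use the seed only for row order; their content
  is deterministic by construction.
* The CLI (`ystr_cli()`) mirrors the workflow as subcommands, demands
  `--seed` for stochastic steps, never overwrites without `--overwrite`,
  and writes a JSON run manifest (command, parameters, package and R
  versions) beside every output set. Configuration files are JSON.

## Known limitations

* Rst excludes DYS385a/b and CNV carriers by default; surveys that
  include them under some convention will differ accordingly.
* The greedy nested-spectrum solver is exact when it succeeds but is not
  a complete search; a pathological chain could be refused even though a
  refinement exists (it errs on the side of refusing).
* MDS of strongly non-Euclidean Rst matrices discards negative-eigenvalue
  structure, as classical scaling always does.
* The permutation test assumes exchangeability of individuals under the
  null; family-structured samples would violate it.
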