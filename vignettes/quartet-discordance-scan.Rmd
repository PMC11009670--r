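---
title: "Quartet-support genome scans under the multispecies coalescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet-support genome scans under the multispecies coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetscan)
```

## The problem

Recombining genomes are mosaics of genealogies. Under neutral evolution the
multispecies coalescent (MSC) predicts that the genealogy ("locus tree")
changes frequently along a chromosome: at drift-recombination equilibrium a
single-genealogy segment is expected to span only `1/(2 Ne r)` bp
(`recombination_free_window()`), which for realistic vertebrate parameter
ranges is 5 bp to a few kb. For species-tree branches that are short in
coalescent units, incomplete lineage sorting (ILS) additionally guarantees
abundant, *stochastic* topological discordance among loci. A multi-megabase
region in which essentially every locus supports one topology — especially a
topology conflicting with the genome-wide species tree — is therefore
incompatible with the MSC and points to something else, such as an ancient
chromosomal rearrangement that suppressed recombination while segregating
through several speciation events (a supergene-like block).

quartetscan provides the statistics and the scan to find such regions in a
collection of per-locus trees, plus a simulator that generates genomes with a
planted discordance-free block so the whole pipeline can be validated
end-to-end on data with known truth.

## Per-locus statistics

**QQS (quadripartition quartet support).** An internal branch plus its four
adjacent branches partitions taxa into groups `A.B | C.D` (outgroup taxa are
always folded into D, so the quadripartition asks for the mutual monophyly of
A and B). For a locus tree, count every quartet with one taxon per group and
classify it as `ab|cd`, `ac|bd` or `ad|bc`; normalising the three counts over
resolved quartets gives supports summing to one. Expectation under the MSC
for a focal internal branch of length `T` coalescent units: the concordant
topology has probability `1 - (2/3) e^{-T}` and each alternative
`(1/3) e^{-T}`; `1/3` apiece is the hard-polytomy signature. `q_main = 1` is
equivalent to mutual monophyly of A and B among the present taxa, which links
the QQS track to the monophyly track (`monophyly_track()`).

**BQS** scores a single bipartition `X | Y` with two-plus-two quartets. It
avoids dependence on adjacent branches but mixes in near-trivial quartets, so
its absolute level is not comparable across clades.

**Counting.** Two independent implementations are provided. The default
(`method = "fast"`) classifies all quartets at once through the four-point
condition on topological (unit-branch-length) path distances: among the
three pairwise-distance sums, the strictly smallest identifies the displayed
split, and equality of all three marks a quartet left unresolved by a
polytomy. This is exact, handles non-binary trees, and is fully vectorised.
A per-edge combinatorial scheme was considered and rejected: the set of
edges separating one quartet forms a path, so summing simple per-edge side
counts over-counts quartets whose separating path is longer than one edge.
`method = "brute"` prunes each quartet and reads its cherry — slow,
transparent, and the oracle the test suite compares against. Unresolved
quartets are counted separately and excluded from normalisation (a strict
mode rejects non-binary trees outright); loci missing a whole group yield
`NA`, never zero, so downstream averages skip them.

## The window scan

For each scanned branch the per-locus QQS values form a genome-ordered track.
Windows cover `w = 20` consecutive qualifying loci (missing loci are dropped
first, so every window averages exactly `w` values), slide one locus at a
time, and never span chromosomes. With `mu` the genome-wide mean of per-locus
QQS and `sigma` a null scale, each window mean `Q_i` is standardised to
`Z_i = (Q_i - mu) / sigma` and assigned `p_i = min(F(Z_i), 1 - F(Z_i))` with
`F` the standard normal CDF — a two-tailed construction of size `2 alpha` at
threshold `alpha`. The p-values are Benjamini-Hochberg corrected per branch,
and maximal runs of windows with `p_adj < 0.01` become outlier regions
(`call_outlier_regions()`; by default only overlapping or abutting windows
merge, `max_gap_loci = 0`).

Two choices deserve comment:

* `sigma` is, by default, the standard deviation of the window means
  themselves rather than the per-locus SD. The window means are the tested
  statistic; scaling by their own SD makes `Z_i` approximately standard
  normal by construction under exchangeability, which is what the normal
  p-value assumes. The per-locus-SD variant is available via
  `sigma_method = "locus"`.
* The focal branch's own windows are *included* in estimating `mu` and
  `sigma`. This is the conservative genome-wide choice; a strong outlier
  region therefore inflates `sigma` and works against its own detection,
  which matters when outlier loci are more than a few percent of the genome
  (see the simulator defaults below).

Sex chromosomes can be excluded from testing by name
(`sex_chromosomes = c("chrZ", "chrW")`), since their coalescent histories are
atypical; tracks are still produced for them.

## Coalescent-HMM post-processing

When a coalescent HMM has decoded per-site posteriors over the four states
S (shallow coalescence), D1 (deep, species-tree topology) and D2/D3 (deep,
discordant), `assign_states()` takes the per-site argmax (ties broken
S > D1 > D2 > D3 — a measure-zero rule, fixed for determinism), and
`window_fractions()` counts states in 100-kb windows tiled from coordinate
zero, reporting `main = (S + D1)/total`, the two alternatives, and the
shallow/deep split of the main support. `ils_level()` summarises a region by
its deep fraction `(D1 + D2 + D3)/total` and its discordant-only fraction
`(D2 + D3)/total`. The latter is compared against the MSC bound: total
discordant-topology probability is `(2/3) e^{-T}`, so no branch length can
push it above `2/3`; `msc_admissible()` computes the bound from the closed
form at `T = 0` and flags larger observed fractions as MSC violations. Both
fractions are reported because published ILS summaries are sometimes
ambiguous about whether deep-but-concordant sites are included; the
admissibility argument is specifically about conflicting topologies, so the
discordant-only fraction is the one checked against 2/3.

## The synthetic-data generator

`simulate_genome()` emulates the structure of a real locus-tree data set:
loci ordered along chromosomes, MSC-distributed topologies with high
discordance, per-locus taxon dropout, gene-tree estimation error, and one
contiguous block in which every locus shares a single topology that
conflicts with the species tree. Gene trees are sampled by the standard
coalescent-within-species-tree algorithm (`sample_msc_gene_trees()`,
implemented in C++ for throughput, with a pure-R reference implementation
cross-checked in the tests).

Default study conditions, chosen once as a realistic desk-scale analogue of
a bird-genome scan and used by the test suite:

* 12 taxa in four groups (3 + 3 + 4 + 2 outgroups) on an ultrametric
  species tree with B sister to A + C, whose focal stem is 0.03 coalescent
  units: the conflicting quadripartition `A.B | C.D` (the one the planted
  block will support) sits at polytomy-level background support
  (`(1/3) e^{-0.03} ~ 0.32`).
* 10,000 loci on two chromosomes, 1 kb long every 10 kb — locus density
  comparable to intergenic-window data sets.
* A 200-locus planted block (2% of loci, matching the order of magnitude of
  the empirical outlier share — the share matters, because the block's own
  windows inflate the genome-wide `sigma` and a much larger planted fraction
  would mask itself).
* The block forces the conflicting topology (A and B sisters). Rather than
  simulating a rearrangement mechanism, the block's species tree is the
  forced topology with all branch lengths stretched 4-fold
  (`block_stretch`), and draws are rejection-sampled to display the forced
  topology exactly: with no added noise every block locus has `q_main = 1`,
  and the block's uniting branches are systematically deeper/longer than
  those of background loci that recover the same clade by ILS chance —
  reproducing the diagnostic branch-length contrast
  (`clade_branch_length_track()`). A uniform time-stretch is used instead of
  adding a constant to internal edges because it preserves ultrametricity
  with a single parameter.
* Estimation error: each tree receives a Poisson(1) number of random NNI
  moves (`phangorn::rNNI`); with 12 taxa an NNI hits the block's focal edge
  rarely, leaving within-block mean QQS near 0.95 — topology error
  calibrated directly, with no sequence simulation. Dropout removes each
  taxon from each locus with probability 0.1 (applied at the sampling stage
  for background loci, which is distributionally identical to pruning by the
  coalescent's marginal consistency; block loci are pruned after the
  topology rejection step so the forced topology refers to the full taxon
  set).
* Background loci are i.i.d. draws — the conservative exchangeable null that
  the window test assumes; an `autocorrelation` knob (probability of reusing
  the previous genealogy) exists for robustness experiments and defaults to
  off.

What the generator does *not* emulate: linked coalescent correlation along
the chromosome (SMC-style), alignment/estimation branch-length error,
gene flow, or rate variation. Passing the planted-block recovery test
therefore shows that the scan detects a suppressed-recombination signature
against an honest MSC null of the stated size — not that it is robust to
every real-data nuisance.

## Numerical and degenerate-input choices

* Quartet states use integer unit-branch distances; ties are exact integer
  equalities, so no floating-point tolerance enters the counters.
* Normalised QQS sums to 1 within 1e-12 whenever defined; undefined loci
  (absent group, all quartets unresolved) propagate `NA`.
* `msc_window_test()` refuses `sigma <= 0` (a degenerate constant genome).
* Windowing requires at least `w` qualifying loci per chromosome; smaller
  chromosomes contribute no windows and are logged.
* Posterior rows must sum to 1 within 1e-6 by default (read tolerance is a
  parameter); site coordinates must be strictly increasing per chromosome.
* Locus tables are 1-based inclusive; BED exports are 0-based half-open.
* `wf_persistence()` treats loss and fixation as absorbing and returns
  exactly 0 when the allele starts fixed or lost; the default initial
  frequency 1/2 (`k0 = N`) is an explicit modelling assumption for
  rearrangement-persistence questions, made visible in the arguments. The
  persistence probability of a specific published scenario depends on that
  assumption (and on conditioning choices that are rarely stated), so the
  function reports its Monte-Carlo estimate with a binomial SE and leaves
  scenario interpretation to the user.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen as the package's own validation conditions: 10,000 MSC draws for the
polytomy-limit QQS mean; 200 random trees of at most 14 taxa for
counter-oracle agreement; one 5,000-locus null genome for test calibration
(raw rejection rate within 0.08 of `2 alpha` at `alpha = 0.05` — about 3 SE
given that overlapping windows of 20 loci carry roughly `n/(2w)` independent
draws — and BH rejections below 1%); 100 seeded 10,000-locus genomes for
planted-block recovery (region must overlap truth with both boundaries
within 20 loci in at least 95 runs); 12,500 draws per point of the
`1 - (2/3) e^{-T}` concordance curve; 20,000 Wright-Fisher replicates against
an exact 11-state Markov chain; and a 30-taxon scaling regression with
log-normal branch noise recovered within 5%.

## Limitations

* The scan's null is exchangeability of loci; genuinely autocorrelated
  discordance (linked selection, large inversions elsewhere) makes the raw
  test anticonservative. The BH step and the contiguity requirement for
  regions absorb some of this, but calibration on real genomes should be
  checked per branch, e.g. from the empirical Z distribution.
* QQS attributes support to a quadripartition, so branches adjacent to a
  true outlier branch also show elevated signal; interpreting which branch
  drives a region needs the per-branch comparison, not a single track.
* The region caller reports maximal significant runs; its boundaries are
  window-resolution (about `w` loci), not breakpoint estimates.
* `quartet_score()` enumerates all shared-taxon quartets, which is fine to a
  few dozen taxa but quadratic-plus beyond that; the taxon-removal
  experiment is intended for candidate-tree comparison at that scale.
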