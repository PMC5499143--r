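---
title: "Measuring selection for translational accuracy with stratified codon-enrichment tests"
author: "akashi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection for translational accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akashi)
```

## The model

Mistranslation wastes resources and can produce toxic misfolded
protein. If some synonymous codons are translated more accurately than
others — for instance because their cognate tRNAs are abundant and
near-cognate competitors are rare — selection should concentrate those
codons at amino-acid sites where an error is most costly. Evolutionary
conservation is the operational proxy for "costly": a site that has not
changed between orthologs is assumed to be under stronger purifying
selection than one that has.

The Akashi test formalises this as a within-gene association test.
For a gene $g$, classify codon sites as conserved ($C$) or variable
($V$) and each codon as optimal or nonoptimal; the per-gene table
$(a_g, b_g, c_g, d_g)$ counts (optimal, nonoptimal) codons at ($C$,
$V$) sites. Pooling with the Mantel–Haenszel estimator,

$$\mathrm{OR}_{MH} = \frac{\sum_g a_g d_g / N_g}{\sum_g b_g c_g / N_g},$$

tests the association *within* genes, so gene-level differences in
expression, GC pressure or mutational bias cannot create a spurious
signal on their own. Significance uses the MH chi-square with one
degree of freedom. The same machinery, with each codon in turn playing
the "optimal" role against its synonymous family peers, yields a
per-codon enrichment scan for any binary site partition
(conserved/variable, domain/nondomain, stem/loop), and those per-codon
odds ratios can be averaged over several ortholog comparisons to judge
robustness across sister species.

## Site classification variants

**Pairwise.** A column of a two-species protein alignment is conserved
when both residues are present and identical, variable when present and
different, excluded when gapped or when a codon contains an ambiguous
base. Ambiguous bases are never guessed.

**Phylogeny-based.** A variable site in a pairwise comparison may have
changed on the lineage of the species under study, in which case the
codon we observe may reflect the pre-substitution state rather than
synonymous selection. On a ((principal, sister), outgroup) trio,
single-column parsimony resolves the lineage: sites with
principal = outgroup ≠ sister changed on the sister branch and are the
only variable sites used; principal-branch changes, changes that
cannot be separated from the internal/outgroup branches
(principal = sister ≠ outgroup), and three-way differences are all
excluded. Conservation requires all three residues identical — a site
conserved between principal and sister but different in the outgroup is
not counted in either class. The classifier is validated against an
exhaustive Fitch enumeration over all $20^3$ amino-acid columns in the
test suite.

**Optimality-tied.** Even a sister-lineage amino-acid change can flip a
codon between favored and disfavored states. This variant keeps a
variable site only when (i) the two codons share the same third
(silent) base, (ii) both codons' families have the same favored third
base, and (iii) when the codons differ at both first and second
positions, every intermediate codon on *both* substitution orderings is
a sense codon satisfying (i) and (ii). We read "all reconstructed
pathways" literally: a pair is dropped if any ordering passes through a
stop codon or a family with a different (or undefined) favored base.
The favored base of a family is the unique third base of its
significant optimal codons; families whose optimal codons disagree on
the third base are treated like families without one, and sites in them
are dropped with an explicit reason code.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| ortholog identity filter | > 60 % | minimum pairwise identity; the denominator counts columns with no gap in either sequence (configurable to full alignment length) |
| expression floor | > 100 | raw expression defining "expressed"; per-gene score is the mean of log10(value) over expressed experiments only |
| expression quantile | 0.20 | fraction of ranked genes in the high- and low-expression sets; ties broken by stable gene-id order |
| significance level α | 0.05 | two-sided, per codon; no multiple-testing correction by default (a Benjamini–Hochberg option exists) because each codon's call is reported individually |
| HGC/LGC boundary | GC ≥ 0.60 | whole-CDS GC, boundary inclusive to the high-GC class |
| strong-pairing threshold | 0.90 | minimum base-pairing probability for a paired third base to make an S-codon; with no probabilities, any paired base counts |
| domain region length | 100 codons | first/last domain windows and flank windows; shorter regions rejected |
| sliding window | 9 nt / step 3 | GC and GC3 windows inside extracted regions |
| positional window | 5 aa | adjacent windows pooled across genes |

There is no published numerical definition of "strongly paired", so the
0.9 threshold is exposed rather than asserted as ground truth. Sixfold
families (Leu, Ser, Arg) are single synonymous families by default;
`split_sixfold = TRUE` everywhere splits them into their 2- and 4-codon
blocks for sensitivity analysis.

## Numerical conventions

* The MH point estimate is computed as-is whenever both pooled sums are
  positive; it is robust to zero cells. When a pooled numerator or
  denominator is exactly zero the estimate is undefined (`NA`) unless a
  finite value is explicitly requested, in which case 0.5 is added to
  every cell of every informative stratum and the result flagged.
* The MH chi-square applies the Yates 0.5 correction only when
  $|A - E| \ge 0.5$, matching the convention of R's
  `mantelhaen.test`, which serves as the independent oracle in the
  tests.
* A stratum is informative when both row and both column sums are
  positive; non-informative strata are counted and ignored by the
  estimator (they contribute nothing to either sum).
* Per-codon odds ratios in the expression contrast use the Haldane
  0.5-in-every-cell correction only when a cell is zero, flagged.
* ENC follows Wright's estimator with degeneracy groups
  (9 twofold, 1 threefold, 5 fourfold, 3 sixfold); a family needs at
  least two counted codons to contribute; a missing threefold group is
  imputed as $(\bar F_2 + \bar F_4)/2$; any other empty group makes the
  statistic undefined; values are clamped to $[20, 61]$.
* Averaging of per-codon odds ratios across comparisons is arithmetic
  on the natural scale (a log-scale geometric mean is available);
  undefined values are skipped and counted.
* Stop codons are excluded from per-gene GC3, ENC, Fop and all codon
  counts. The low-level `gc3_content()` operates on whatever in-frame
  sequence it is given, so callers strip the stop codon when that is
  the intent.
* Transcript thirds are blocks of $\lfloor L/3 \rfloor$ codons with the
  remainder in the last block. Positional windows are indexed on the
  ungapped principal-CDS coordinate; gap columns are skipped without
  shifting window boundaries, and trailing incomplete windows are
  dropped.

## The synthetic-data generator

`simulate_bundle()` emits ortholog pairs or trios plus every companion
file the readers consume. Per gene: a conservation mask with
$P(\text{conserved}) = f_c$; ancestral amino acids uniform over the 18
degenerate families; the principal codon optimal with probability
$p_c$ at conserved and $p_v$ at variable sites (nonoptimal codons
uniform over the family's remaining codons); nonsynonymous
substitutions applied per branch at variable sites (sister branch with
probability 1 by default, principal and outgroup 0). The generative
Akashi odds ratio is therefore
$[p_c/(1-p_c)]/[p_v/(1-p_v)]$ — 2.333 at the default
$p_c = 0.7, p_v = 0.5$ — and the recovery of this closed form, the
calibration of the null ($p_c = p_v$), and the localisation of an
injected positional change-point are all asserted in the test suite.

Design choices worth knowing:

* **Domain GC3 shift.** `delta_dom` adds exactly that amount to the
  expected third-base GC fraction at domain sites: AT-ending codons are
  resampled to a GC-ending family codon at rate
  $\delta/(1-g)$, where $g$ is the analytic baseline GC3 of the site's
  class. This keeps the shift exact in expectation but slightly
  perturbs codon optimality inside domains, so very large `delta_dom`
  values couple the composition and accuracy signals — intentional, as
  that is precisely the confounding the stratified tests exist to
  dissect.
* **Expression model.** Per experiment,
  $\log_{10}(\text{value}) \sim N(\mu + \beta\,\mathrm{Fop}, \sigma)$
  with $\mu = 3$, $\beta = 8$, $\sigma = 0.3$ over 5 experiments. Fop
  varies across genes only by binomial sampling noise (s.d. ≈ 0.03 at
  300 codons), so $\beta$ is set high enough that the high/low
  expression contrast reflects codon usage strongly, emulating the
  well-documented association between expression level and optimal
  codon frequency.
* **Structures** are balanced hairpin tilings (6-bp arms, 4-nt loops,
  dot spacers) hitting a target paired fraction, with pairing
  probabilities above 0.9 for a `strong_pair_prob` share of paired
  bases. They are a bookkeeping device for the S/L stratification, not
  a thermodynamic model.
* **Reproducibility.** Each gene has its own RNG stream keyed by
  (seed, gene index), so increasing `n_genes` extends a bundle without
  perturbing earlier genes; the same seed reproduces a bundle
  byte-for-byte.

What the generator does **not** emulate: indels (alignments are
gap-free unless you add them), realistic codon substitution processes
(changes are uniform over amino-acid families, not rate-matrix driven),
autocorrelated conservation along the sequence, UTRs, and genuine
thermodynamic mRNA folding. Passing tests therefore demonstrate that
the statistics recover known effects under the stated sampling model —
not that real genomes satisfy that model.

## Problem sizes used in the validation suite

The oracle-equivalence checks run on 1,000 random stratum sets and all
$20^3$ amino-acid trios / $61^2$ codon pairs exhaustively. Monte-Carlo
checks use 200 replicates of 500 genes × 300 codons for the null
calibration, 50 such replicates for parameter recovery, 250 genes for
the positional change-point, and 60 genes of 400 codons for the domain
composition recovery — sizes at which the binomial/Monte-Carlo error is
a few percent of the asserted effect.

## Known limitations

* The phylogeny-based classifier resolves single columns only; it does
  not use joint ancestral reconstruction across sites, so sites with
  principal = sister ≠ outgroup are discarded rather than polarised.
* Optimal-codon identification uses one pooled 2×2 per codon
  (chi-square) rather than gene-stratified MH, because genes are not
  paired across the high/low expression classes.
* `correlate()`'s structured permutation assumes equal-sized groups
  (complete codon × species matrices).
* The package consumes alignments, domain coordinates, folds and tRNA
  counts as inputs; it does not run aligners, HMM scans, folding or
  tRNA detection.
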