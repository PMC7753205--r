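---
title: "Methods: classifying cis/trans regulatory divergence from hybrid allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying cis/trans regulatory divergence from hybrid allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistrans)
library(dplyr)
```

## The model

Consider a gene in a cross between two diverged genotypes (call the
parents P1 and P2). Write its *cis* effect $c$ and *trans* effect $t$,
both in log2 units of the P1/P2 expression ratio. In the F1 hybrid the
two alleles share one trans environment, so the allelic ratio reflects
only the cis effect; the expected fraction of reads carrying the P1
allele is

$$p_{F1} = \frac{2^{c}}{1 + 2^{c}}.$$

In the parents (observed through an *in-silico hybrid*, i.e. an
equal-amount computational mix of the two parental RNA samples, which
represents the additive mid-parent expectation) the full divergence
$c + t$ is visible:

$$p_{mix} = \frac{2^{c+t}}{1 + 2^{c+t}}.$$

The trans effect is thus defined as the part of the parental log2 ratio
not explained by the F1 allelic ratio. Three per-gene tests interrogate
this structure:

| Test | Data | Null | Significance means |
|------|------|------|--------------------|
| P | mix counts $(m_1, m_2)$ | binomial, $p = 1/2$ | parental divergence |
| H | F1 counts $(f_1, f_2)$ | binomial, $p = 1/2$ | cis divergence |
| T | 2×2 table $[[f_1, f_2], [m_1, m_2]]$ | Fisher exact | trans divergence |

Both binomial tests are two-sided by the minimum-likelihood rule (sum of
all outcome probabilities no larger than that of the observation), the
convention implemented by `binom.test`; divergence in either direction is
biologically meaningful. P-values are Benjamini–Hochberg adjusted
*within each comparison* across all tested genes, and $q < \alpha$
(default 0.05) defines significance. The seven-way rule table is then:

| P | H | T | sign agreement | category |
|---|---|---|----------------|----------|
| ✓ | ✓ | – | | cis-only |
| ✓ | – | ✓ | | trans-only |
| ✓ | ✓ | ✓ | same | cis + trans |
| ✓ | ✓ | ✓ | opposite | cis × trans |
| – | ✓ | ✓ | | compensatory |
| – | – | – | | conserved |
| any other pattern | | | | ambiguous |

Sign agreement compares $\log_2\frac{f_1 + 0.5}{f_2 + 0.5}$ with the
analogous mix ratio; the 0.5 pseudocount keeps zero counts finite. An
exactly zero ratio is treated as agreement (and reported); with real
counts its probability is negligible. A gene with a zero-count sample is
untestable and routed to `ambiguous`. The rule table is total: every
significance pattern maps to exactly one category, which the test suite
verifies by exhaustive enumeration against an independent brute-force
implementation.

## From reads to gene profiles

The classifier consumes per-gene bi-parental counts built in four steps,
each with the thresholds exposed as arguments:

1. **Variant filtering** (`filter_variants`): bi-allelic SNPs at which
   the parents are homozygous for different alleles, with genotype
   quality > 20 and depth > 5 in both parents (strict inequalities).
2. **Mapping-bias filtering** (`filter_biased_snps`): a mixed parental
   DNA sample should show 1:1 allele representation at every SNP; sites
   with a two-sided exact binomial p-value < 0.05 are removed. Raw
   p-values are used deliberately — the filter should be aggressive, and
   an FDR correction would retain more biased sites.
3. **In-silico hybrid** (`build_insilico_mix`): both parents contribute
   an equal effective library size, either by scaling the larger library
   (rounding half-to-even so neither allele is systematically inflated)
   or by hypergeometric down-sampling without replacement.
4. **Aggregation** (`aggregate_to_genes`): SNP counts are summed over
   the gene body (full genomic extent, both strands — the natural
   reading of summing reads in the "body region"; a SNP inside two
   overlapping genes counts toward both, with a message). Genes with
   fewer than 2 informative SNPs are excluded, as are genes whose mean
   total count falls outside the open interval (10, 1000) — the lower
   bound removes power-less genes, the upper guards against collapsed
   repeats and PCR artifacts. Whether the expression filter belongs
   before allelic testing is a genuinely open ordering question; it is
   applied before classification here (consistency between stages) and
   can be disabled with `expr_bounds = NULL`.

## Duplication modes and WGD ages

`assign_modes` classifies every positioned gene from an all-to-all
protein homology search, following the MCScanX conventions: hits are
filtered (e-value ≤ 1e-10, top 5 non-self hits per gene, both
configurable), and the override priority is
**wgd > tandem > proximal > dispersed**, with **singleton** for genes
with no retained hit. "Interrupted by fewer than 20 genes" is read as
rank distance ≤ 20 (distance 1 = tandem, 2–20 = proximal); the bound is
the `proximal_max_gap` argument for users who prefer the strict
intervening-count reading.

Collinear blocks come either from an MCScanX `.collinearity` file
(`read_collinearity`) or from `detect_collinearity`, a simplified
synteny chainer: anchors (homology hits placed in the two rank spaces)
are chained monotonically — either orientation in the second genome —
with per-step rank gaps ≤ `max_gap` (default 25), and chains with ≥
`min_anchors` (default 5) anchors are blocks. Chains are extracted
longest-first by dynamic programming. Same-chromosome hit pairs at rank
distance < 20 are tandem/proximal duplicates, not synteny anchors, and
are excluded from chaining — without this, any dense run of tandem
duplicates would chain into a spurious "block". The chainer is validated
against an exhaustive-recursion oracle on small anchor sets.

WGD ages: each block's mean Ks (synonymous substitutions per synonymous
site, a proxy for duplication age) is clustered into $k = 3$ groups. One
dimension permits an exact solution: optimal 1-D k-means clusters are
contiguous in sorted order, so the package solves the k-means objective
globally by dynamic programming over contiguous partitions rather than
running the random-restart Lloyd heuristic. This is deterministic,
needs no seed, and provably attains the optimum that a well-initialized
heuristic only approximates (the test suite checks equality with an
exhaustive partition search). A gene is **young** iff every block
containing it falls in the cluster with the smallest mean Ks; fewer than
$k$ distinct Ks values trigger a quantile-cut fallback.

## Cross-tabulation and enrichment

`crosstab` counts genes per duplication mode × regulatory category, with
row percentages rounded half-up to 2 decimals (the presentation
convention of published tables; base R rounds half-to-even). Two
chi-squared constructions, both without continuity correction, cover the
standard claims: `cis_vs_trans_test` is the 1-df goodness-of-fit of the
(cis-only, trans-only) counts against 1:1, and `mode_vs_genome_test` is
the 2×2 comparison of a mode's category rate against the rest of the
genome. `deg_summary` tabulates differential-expression counts as
percentages of expressed genes (1 decimal, half-up).

`enrich` performs the one-tailed hypergeometric over-representation
test: $p = P(X \ge k)$ for $X \sim \mathrm{Hyper}(N, K, n)$ with
universe $N$ = expressed genes (not the whole genome — the background
must reflect what could have been observed), $K$ = term size within the
universe, $n$ = query size, $k$ = overlap. Terms with $K < 5$ are
removed before testing; BH runs across the retained terms, applied per
annotation source (GO and Pfam separately), and $q < 0.05$ flags
significance. No GO-hierarchy propagation is performed.

## The synthetic-data generator

`simulate_dataset` emulates the data structure the pipeline consumes:
per-gene architectures drawn from a category mix, negative-binomial
total depth (mean $\mu$, variance $\mu + \phi\mu^2$ — the standard
RNA-seq overdispersion model), binomial allelic sampling at $p_{F1}$ /
$p_{mix}$, multinomial splitting over the gene's SNPs with equal weights
(per-SNP coverage is irrelevant downstream because counts are re-summed),
and a mixed-DNA control drawn binomial at 1:1 except for a configurable
fraction of mapping-biased SNPs. One RNG stream per sample type is
derived from the master seed, so the same seed gives bit-identical
output.

Defaults are chosen once as realistic study conditions: the category mix
follows the genome-wide proportions observed in a wild × cultivated
soybean cross over the six generating architectures (58% conserved, 22%
trans-only, 9% cis-only, the rest split among the complex types); effect
magnitudes are uniform on [0.5, 2] log2; per-gene depth is 300 reads
(within the 100–1000 range typical of per-gene allelic coverage), with
dispersion 0.05; 2–6 SNPs per gene; 50 DNA reads per SNP; 5% of SNPs
mapping-biased at allele probability 0.8.

`simulate_genome_layout` plants duplication modes recoverable by
construction: each collinear block (6 anchor pairs, every third laid out
antiparallel) occupies its own chromosome pair with a Ks regime cycling
through ~0.1 / ~0.6 / ~1.4; tandem pairs sit at adjacent ranks; proximal
pairs are separated by 1–19 unrelated filler genes; dispersed partners
are scattered across dedicated chromosomes in groups smaller than
`min_anchors` so they cannot chain into a block. Dense, genuinely
collinear arrangements of non-WGD pairs are thereby avoided by design —
with densely packed pairs, long monotone runs are combinatorially
unavoidable and would be *correctly* called collinear.

What the generator does **not** emulate: read-level artifacts (FASTQ,
alignment, duplicate reads), allelic mapping bias at the read level
(bias is modeled directly as a skewed DNA-control probability),
correlated SNP coverage within a gene, biological replicates (counts are
replicate-pooled, as in the exact-test framework), and isoform
structure. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated sampling model, not robustness to
alignment pathologies.

## Numerical choices and edge cases

- Two-sided binomial p-values use the minimum-likelihood rule with the
  same relative tolerance as `binom.test` when comparing point
  probabilities.
- BH is applied per comparison (P, H, T separately); applying it jointly
  would couple the three tests' thresholds for no inferential gain.
- `scale`-mode mixing rounds half-to-even; `subsample` mode uses a
  sequential multivariate hypergeometric draw.
- Zero-depth SNPs are untestable in the bias filter and removed with a
  logged reason; zero-count samples route a gene to `ambiguous` with
  p = 1 rather than crashing.
- Empty inputs give empty, correctly-typed outputs throughout
  (headers-only files from `write_fixture_bundle`, empty tibbles from
  `classify_all`, an all-zero `crosstab`).

## Problem sizes used by the checks

The shipped verification runs use 2,000 genes at depth 10,000 for
category recovery (effect magnitudes ≥ 1 log2), 2,000 all-conserved
genes at depth 500 for the null calibration, 10,000 SNPs at DNA depth 50
for the bias-filter calibration, 400-gene planted layouts for
duplication-mode recovery, and 1,000 random query sets over a 500-gene
universe with 40 terms for the enrichment null. These sizes give stable
rates (binomial standard errors well under a percentage point) while
running in about a minute.

One calibration subtlety deserves note: the exact binomial bias filter
is conservative by discreteness. At a fixed DNA depth of 50 its true
size at nominal $\alpha = 0.05$ is 3.28%, and no fixed desk-scale depth
brings it near 5%. The calibration check therefore compares the
empirical removal rate with the *analytically computed* exact size at
the simulated depth (and confirms it never exceeds the nominal level),
rather than demanding a rate near 5% that an exact test cannot produce.

## Known limitations

- Replicate structure is pooled; overdispersed replicate-aware tests
  (beta-binomial) are out of scope by design.
- Reads covering two nearby SNPs of one gene are counted once per SNP;
  the summation inherits that double-counting from the count-level
  input.
- The synteny chainer is a simplified single-pass DP, not the full
  MCScanX scoring model; for publication-grade synteny use MCScanX and
  feed the `.collinearity` file in.
- Ks computation itself (from coding sequences) is consumed, not
  performed.
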