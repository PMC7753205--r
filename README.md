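# cistrans

Classify the regulatory basis of gene-expression divergence between two
genotypes from allele-specific read counts in their F1 hybrid.

When two diverged genotypes are crossed, both alleles of every gene sit in
the same nucleus of the F1 and are exposed to the same *trans*-acting
environment. An allelic imbalance inside the F1 therefore indicates
*cis*-regulatory divergence (linked, allele-local changes), while a
parental expression difference that disappears in the F1 indicates
*trans*-regulatory divergence (diffusible factors). `cistrans` implements
the standard three-test decomposition on per-gene bi-parental read counts:

- **P comparison** — exact binomial test of the allelic ratio in an
  *in-silico hybrid* (an equal-amount computational mix of the two
  parents' reads) against 1:1; significance indicates parental divergence.
- **H comparison** — the same test in the F1 hybrid; significance
  indicates *cis* divergence.
- **T comparison** — Fisher's exact test comparing the two ratios on the
  2×2 table `[[f1_p1, f1_p2], [mix_p1, mix_p2]]`; significance indicates
  *trans* divergence.

P-values are Benjamini–Hochberg adjusted within each comparison across all
tested genes, and the significance pattern (with the sign agreement of the
two log2 allelic ratios) places each gene into one of seven categories:
*cis*-only, *trans*-only, *cis + trans*, *cis × trans*, compensatory,
conserved, or ambiguous.

Around that core the package provides the full analysis pipeline used in
wild/cultivated crop comparisons:

- per-SNP allele-count ingestion (ASEReadCounter-style TSV), parental SNP
  filtering from a VCF (bi-allelic, homozygous-different, GQ > 20,
  DP > 5), removal of mapping-biased SNPs by an exact binomial test on a
  mixed-DNA control, in-silico hybrid construction, and gene-body
  aggregation with the ≥2-SNP and expression filters;
- gene duplication-mode assignment (singleton / dispersed / proximal /
  tandem / WGD) from BLAST hits and gene order, with collinear-block
  detection or an MCScanX `.collinearity` file, and young/old WGD age
  classes from exact 1-D k-means (k = 3) on per-block mean Ks;
- mode × category cross-tabulation with chi-squared comparisons, and DEG
  summary tables;
- one-tailed hypergeometric GO/Pfam over-representation with a term-size
  filter and BH-FDR;
- a synthetic-data generator with known cis/trans architectures and
  planted duplication modes, so every stage is testable without
  sequencing data.

## Worked example

```r
library(cistrans)

# simulate a cross: 200 genes, known architectures, then classify
sim <- simulate_dataset(sim_config(n_genes = 200, seed = 11))
rna <- dplyr::filter(sim$snp_counts, sample != "MIX_DNA")
profiles <- aggregate_to_genes(rna, sim$gene_models, expr_bounds = NULL)
calls <- classify_all(profiles, alpha = 0.05)
glance(calls)
#> # A tibble: 1 × 9
#>   n_genes alpha cis_only trans_only cis_plus_trans cis_x_trans compensatory
#>     <int> <dbl>    <int>      <int>          <int>       <int>        <int>
#> 1     192  0.05       20         42              7           1            6
#> # ℹ 2 more variables: conserved <int>, ambiguous <int>
```

192 of the 200 simulated genes survive the ≥2-informative-SNP filter; at
the default per-gene depth of ~300 reads most *cis*-only and *trans*-only
architectures are recovered while weak-effect genes fall into `conserved`
or `ambiguous` — power grows with depth. `autoplot(calls)` draws the
classic mix-vs-F1 log2-ratio scatter coloured by category.

Published count tables can be re-analysed directly. For the soybean
wild × cultivated cross shipped as a worked example:

```r
xt <- crosstab_from_counts(soybean_crosstab_counts())
xt$proportions[xt$proportions$mode == "wgd", c("mode", "cis_only", "trans_only")]
#> # A tibble: 1 × 3
#>   mode  cis_only trans_only
#>   <chr>    <dbl>      <dbl>
#> 1 wgd       6.98       17.9
cis_vs_trans_test(428, 1100)
#> # A tibble: 1 × 3
#>   statistic    df  p_value
#>       <dbl> <int>    <dbl>
#> 1      296.     1 3.09e-66
```

WGD duplicates show two and a half times more *trans*-only than *cis*-only
divergence (17.93% vs 6.98%, χ² ≈ 295.5), the signature of duplicates
retained in shared regulatory networks.

A YAML-configured end-to-end run (`run_pipeline()`) and a thin CLI
(`inst/cli/cistrans-pipeline.R`, subcommands `simulate` and `run`) wrap
the same functions; see the methods vignette
(`vignettes/cistrans-methods.Rmd`) for the model, parameter and design
details.

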