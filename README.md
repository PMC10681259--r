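# ripscore

Identify the RNA and protein partners of an RNA-binding protein from
immunoprecipitation experiments.

ripscore implements the two statistical workflows such a study runs after
read counting and protein quantification are done, plus the set statistics
that turn their outputs into biological claims:

* **RIP-seq enrichment (`rip_enrichment()`).** Gene-level IP vs input
  counts are normalized by median-of-ratios size factors and tested with a
  per-gene negative-binomial Wald test (log-link GLM with size-factor
  offsets, moment dispersions moderated toward a common center). Candidate
  targets are ranked by the composite score

  V = log2FC × (−log10 p)

  and selected by a strict threshold (V > 50 by default), so a target must
  be both strongly and confidently enriched.
* **Label-free AP-MS interactor calling (`interactome_pipeline()`).**
  MaxQuant-style LFQ protein groups are filtered on peptide evidence and
  decoy/contaminant flags, log2-transformed, subjected to a 60% valid-value
  rule in at least one group, completed by down-shifted Gaussian imputation
  (per-sample Normal(m − 1.8·s, (0.3·s)²), the standard treatment of
  below-detection-limit missingness), and tested with an s0-moderated
  t-statistic (d = Δ/(se + s0)) against a permutation null; the significance
  cutoff is the smallest |d| whose estimated FDR (mean permutation count /
  observed count) is at or below the target (0.01 by default).
* **Set statistics (`category_enrichment()`, `overlap_count()`,
  `core_intersection()`, `densitometry_fold_change()`).** Log-space
  upper-tail hypergeometric over-representation with BH adjustment, exact
  set overlaps with attached p-values, and western-blot densitometry fold
  changes with a t-test on log ratios.
* **Synthetic data with planted truth (`simulate_ripseq()`,
  `simulate_proteome()`, `simulate_annotation()`).** Seeded generators that
  emulate the two assay designs — including missing-not-at-random LFQ
  dropout — so every stage's operating characteristics (null calibration,
  sensitivity, false-discovery proportion) are testable without any
  external data.

Results are tibbles that work with the pipe, `tidy()`, `glance()` and
`autoplot()`.

## Worked example

```r
library(ripscore)

# RIP-seq: 2000 genes, 3 IP vs 3 input, 5% planted targets at log2FC = 3
sim <- simulate_ripseq(n_genes = 2000, enriched_frac = 0.05, seed = 1)
res <- rip_enrichment(sim$counts, sim$design)
glance(res)
#> # A tibble: 1 × 7
#>   n_genes n_selected vfactor_threshold p_source median_dispersion n_unconverged
#>     <int>      <int>             <dbl> <chr>                <dbl>         <int>
#> 1    2000         89                50 p                   0.0437             0

head(tidy(res)[order(-res$vfactor), ], 3)
#>   gene_id   base_mean log2fc        p     padj vfactor selected
#> 1 gene_1946     1968.   3.46 1.15e-48 1.36e-45    166. TRUE
#> 2 gene_0581     5653.   3.24 1.36e-48 1.36e-45    155. TRUE
#> 3 gene_0474     1390.   3.31 1.55e-44 7.76e-42    145. TRUE
```

The 89 selected genes are those with Vfactor above 50: planted targets
(true log2FC 3) dominate the top of the ranking, with p-values small enough
that the composite score is driven by both terms.

```r
# AP-MS: 1000 protein groups, 6 bait vs 3 control, 5% planted interactors
ps <- simulate_proteome(n_groups = 1000, seed = 1)
vr <- interactome_pipeline(ps$table, ps$design, seed = 1)
glance(vr)
#> # A tibble: 1 × 7
#>   n_groups n_enriched n_depleted cutoff   fdr    s0 n_perm_used
#>      <int>      <int>      <int>  <dbl> <dbl> <dbl>       <int>
#> 1      865   46          0   3.87  0.01   0.1          83

autoplot(vr)   # volcano with the significant interactors highlighted
```

Of the 1000 simulated groups, 865 survive the evidence and valid-value
filters; 46 are called as bait-enriched interactors at permutation FDR
0.01 with an |d| cutoff of 3.87 estimated from the 83 distinct
bait/control relabelings.

```r
# shipped fixture: consensus Ssd1 targets vs eIF2A RIP-seq target flags
core <- ssd1_core_targets()
overlap_count(core$gene, core$gene[core$eif2a_target])
#> # A tibble: 1 × 3
#>       k   n_a   n_b
#> 1     8    11     8
```

Eight of the eleven consensus Ssd1 target mRNAs are also eIF2A targets —
the kind of overlap statement `overlap_count()` is for.

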