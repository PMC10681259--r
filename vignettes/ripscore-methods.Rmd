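---
title: "Methods: enrichment scoring, interactor calling, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment scoring, interactor calling, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripscore)
```

ripscore identifies the RNA and protein partners of an RNA-binding protein
from two kinds of immunoprecipitation experiments: RIP-seq (which mRNAs are
enriched in the IP fraction relative to total RNA?) and label-free AP-MS
(which proteins are enriched in bait pull-downs relative to mock controls?).
This vignette documents the statistical models, the tunable parameters, the
synthetic data used for validation, and the design decisions taken where
more than one defensible choice existed.

## The RIP-seq enrichment model

### Normalization and the count model

Raw gene-level read counts from IP and input libraries are normalized with
median-of-ratios size factors: for genes with all-positive counts, each
sample's counts are divided by the per-gene geometric mean and the sample's
factor is the median of those ratios, rescaled to geometric mean 1. This is
the standard normalization for count data whose majority of genes is not
differentially represented between libraries.

Counts are modeled as negative binomial with gene dispersion $\alpha_g$
(variance $\mu + \alpha\mu^2$). For each gene we fit the two-group GLM

$$\log \mu_{gj} = \log s_j + \beta_{0g} + x_j\,\beta_{1g},$$

with $x_j = 1$ for IP samples, by iteratively reweighted least squares
(shared design, per-gene closed-form $2{\times}2$ solve, vectorized across
genes; at most 100 iterations, convergence when the largest coefficient
change falls below $10^{-8}$). The reported effect is
$\log_2\!\text{FC} = \beta_1/\ln 2$ with its Wald standard error from the
inverse Fisher information, and the p-value is the two-sided normal tail of
their ratio. Zeros are ordinary observations under the GLM; no pseudocounts
enter the fit. Two failure modes are flagged rather than silently patched:
an all-zero condition makes the MLE infinite, so the gene is marked
`degenerate` and its fold change reported from a half-count fallback with
`p = NA`; non-convergence is marked `converged = FALSE` with `p = NA`.

### Dispersion estimation

The raw per-gene estimator is method-of-moments on normalized counts,
computed within each condition and averaged:
$\hat\alpha = (s^2 - \bar q)/\bar q^2$, floored at $10^{-8}$
(`estimate_dispersions()`). With three replicates per condition this
estimator has only four residual degrees of freedom, and plugging it into
the Wald test produces visibly anticonservative null p-values. The pipeline
therefore moderates the per-gene estimates toward a robust common center —
the 5%-trimmed mean of the floored raw estimates — with a prior weight of
10 against the per-gene degrees of freedom (`moderate_dispersions()`). We
deliberately shrink toward a scalar center rather than a fitted
mean–dispersion trend: at the replication levels this package targets, the
data cannot support estimating a trend, and a scalar center already
restores null uniformity (Kolmogorov–Smirnov distance to $U[0,1]$ of
0.02–0.04 at 3v3 in our null simulations, versus ~0.07 unmoderated) while
leaving planted-effect recovery intact. The cost is bias when true
dispersions vary strongly across genes; for deeply replicated designs the
raw estimates can be used directly (`moderate = FALSE`).

### The Vfactor selection score

Ranking candidate targets by fold change alone favors noisy low-count
genes; ranking by p-value alone favors small but precisely measured
enrichments. The composite score

$$V = \log_2\!\text{FC} \times (-\log_{10} p)$$

requires both a large and a well-supported enrichment. Targets are the
genes with $V$ strictly greater than the threshold (default 50; a gene at
exactly the threshold is excluded). Two conventions matter:

* **Which p enters the score.** The raw test p-value is used by default —
  the literal reading of the definition — with `use_padj = TRUE` available
  to score on BH-adjusted values instead. Both columns are always present
  in the output, so either convention can be audited after the fact.
* **Underflow.** p-values below $10^{-300}$ are floored there before the
  logarithm so the score stays finite; the floor is recorded in the result
  attributes.

BH adjustment across genes is reported (`padj`) for conventional FDR
reading, but selection is driven by the Vfactor. No independent filtering
or outlier replacement is applied: every gene in the matrix is tested.

## The AP-MS interactor workflow

The proteomics arm consumes a MaxQuant-style protein-group table with LFQ
intensities for $n$ bait pull-downs (default design 6) and $m \ge 3$
negative controls, and follows the established label-free volcano
workflow. The stage order is part of the contract and enforced at runtime —
each stage records what it produced and refuses input from the wrong
stage:

1. **Evidence filter** — groups supported by a single razor+unique
   peptide, reverse-database hits and contaminants are removed, with
   removal counts kept in a filter log.
2. **log2 transform** — intensity 0 (the "not quantified" convention) and
   `NaN` become explicit missing values.
3. **Valid-value filter** — a group is kept when at least 60% of its
   values are valid in the bait group *or* in the control group
   (`>=` on the exact fraction).
4. **Down-shifted imputation** — missing LFQ values are overwhelmingly
   missing-not-at-random (below the detection limit), so each missing
   value in sample $j$ is drawn from
   $\mathcal N(m_j - 1.8\,s_j,\ (0.3\,s_j)^2)$, where $m_j, s_j$ are that
   sample's observed mean and SD *after* the valid-value filter (the
   post-filter convention keeps the imputation statistics from being
   dragged down by groups that are about to be discarded). Width and
   downshift are in units of the per-sample SD; the seed is required and
   the imputation mask is returned. Because the downshift is 6 widths, an
   imputed value essentially never exceeds the sample mean
   ($\Phi(-6) \approx 10^{-9}$).
5. **Permutation-FDR volcano** — the test statistic is the s0-moderated
   ratio $d = \Delta/(\mathrm{se} + s_0)$ with a pooled-variance Student
   t-test behind it (Welch by flag). The null distribution of $|d|$ comes
   from bait/control label permutations: all distinct relabelings are
   enumerated when there are at most `n_perm` (default 250; a 6v3 design
   has 83 usable relabelings, a 6v6 design 461 after halving
   complement-equivalent splits), otherwise a seeded subsample is used. The observed labeling is
   **excluded** from the null set: with it included the estimated FDR can
   never drop below $1/n_\text{perm}$ ($\approx 0.012$ at 6v3), which
   would make the conventional FDR 0.01 unattainable for any cutoff. The
   cutoff is the smallest $c$ with
   $\widehat{\mathrm{FDR}}(c) = \frac{\text{mean permutation count of } |d| \ge c}
   {\text{observed count of } |d| \ge c} \le \mathrm{FDR}$, after
   enforcing monotonicity of the curve. Interactors are the
   enrichment-side calls ($d > 0$); the depleted side is classed
   separately and never mixed into the interactor list.

Defaults follow common practice for this workflow where the procedure
itself does not pin them: $s_0 = 0.1$, FDR 0.01, width 0.3, downshift 1.8.
The mean of the per-permutation exceedance counts is used by default
(median by flag).

## Set statistics

Category over-representation is the one-sided upper-tail hypergeometric
test (equivalently one-sided Fisher), evaluated in log space via
`phyper(log.p = TRUE)` so that p-values far below $10^{-100}$ remain
exact; BH adjustment is applied across categories. The universe defaults
to the annotated genes and should be set to the tested transcriptome when
one is available — category fractions (the "24% of targets" style of
claim) are reported alongside. Set intersections and pairwise overlaps are
exact set algebra with deterministic ordering, with the hypergeometric
p-value attached when a universe is supplied.

Densitometry fold changes (western-blot validation) divide each lane's
target-band signal by its loading-control signal; each overexpression
replicate's relative abundance is divided by the mean control relative
abundance, and a two-sided one-sample t-test of the log fold changes
against 0 is reported. Pairing against the control *mean* (rather than
lane-by-lane pairing) is the conservative reading of a ratio-of-averages
definition when no pairing is stated.

The package ships one small fixture, `ssd1_core_targets()`: the eleven
mRNAs consistently recovered as Ssd1 targets across published RIP and CRAC
experiments, flagged by whether each was also called as an eIF2A RIP-seq
target (8 of 11 are).

## Synthetic data with planted truth

All operating characteristics are established on seeded generators whose
defaults are fixed once and mirror a realistic small-genome RIP/AP-MS
study; they are pure functions of their configuration and seed.

* `simulate_ripseq()` — 2000 genes, 3 IP vs 3 input replicates, log-normal
  baseline means (median 200 counts, $\sigma_{\log} = 1$), NB dispersion
  0.05, library-size factors uniform on $[0.7, 1.4]$, and a planted
  $\log_2\!\text{FC} = 3$ on 5% of genes when enrichment is requested.
* `simulate_proteome()` — 1000 protein groups, 6 bait vs 3 control,
  latent log2 intensities $\mathcal N(26, 3^2)$ (the typical LFQ range),
  within-group SD 0.5, planted bait shift of 3 log2 units on 5% of
  groups. Missingness is missing-not-at-random by construction: each
  latent value is observed with probability
  $\mathrm{logit}^{-1}(v - 21.5)$, i.e. a detection midpoint 1.5 baseline
  SDs below the mean intensity (about 12% missing cells overall), which
  is precisely the left-censoring the down-shifted imputation assumes. A
  5% fraction of groups carries exactly one razor+unique peptide and 2%
  are flagged, so the evidence filter is always exercised.
* `simulate_annotation()` — a 6000-gene universe with a focal category at
  3% background membership, inflated 8-fold (to ~24%) within a supplied
  target set.

What these generators do *not* emulate: count outliers and batch effects
(RIP-seq), correlated contaminant structure, peptide-level effects and
intensity-dependent variance (AP-MS), or hierarchical category overlap (GO
DAGs). Passing the recovery suite therefore demonstrates that the
machinery is correct and calibrated under its stated model, not that real
data meet that model.

### Operating characteristics asserted by the test suite

With the defaults above and fixed seed suites (five seeds for recovery
properties, problem sizes 1000–2000 rows chosen so the whole suite runs in
seconds):

* **Null calibration.** With no planted truth, downstream RIP p-values
  are near-uniform (KS < 0.05), the fraction of genes at padj < 0.05
  stays within binomial noise of zero, fewer than 0.5% of genes exceed
  Vfactor 50, and the interactor set at FDR 0.01 is empty in at least
  95% of 100 seeded runs.
* **Recovery.** Planted RIP targets ($\log_2\!\text{FC} = 3$, 5% of
  genes) are selected at Vfactor > 50 with mean sensitivity $\ge 0.8$ and
  false-discovery proportion $\le 0.1$; planted interactors (+3 log2, SD
  0.5) are called at FDR 0.01 with mean sensitivity $\ge 0.9$ and FDP
  $\le 0.05$ (sensitivity among groups surviving the valid-value filter —
  a group whose evidence was censored below the detection limit is not
  testable by any method).
* **Oracle equivalence.** Size factors, BH, the hypergeometric tail and
  the NB Wald fit match independent brute-force implementations
  (loop-based median-of-ratios, step-up BH from the definition, log-gamma
  summation, and direct NB likelihood maximization) at the tolerances
  stated in the tests.

## Known limitations

* The Wald test with moderated dispersions is calibrated in our
  simulations but, like any plug-in Wald procedure at $n = 3$ per group,
  is not exact; strongly mean-dependent dispersion would call for a
  trended model this package intentionally omits.
* Permutation FDR with few controls is granular: at 6v3 only 83 usable
  relabelings exist, so the estimated FDR takes discrete values and the
  cutoff is conservative when many strong effects contaminate the
  permuted null.
* The hypergeometric enrichment p-value depends on the chosen universe
  and category sizes; published p-values from web tools are generally not
  reproducible without the database state behind them, and the package
  makes no attempt to do so.
* Densitometry testing treats replicates as independent; lane-pairing
  information, when available, would give a more powerful paired test.

## A worked example

```{r example, eval = FALSE}
library(ripscore)

sim <- simulate_ripseq(n_genes = 2000, enriched_frac = 0.05, seed = 1)
res <- rip_enrichment(sim$counts, sim$design)
glance(res)
autoplot(res, type = "vfactor")

ps <- simulate_proteome(n_groups = 1000, seed = 1)
vr <- interactome_pipeline(ps$table, ps$design, seed = 1)
glance(vr)
autoplot(vr)
```
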