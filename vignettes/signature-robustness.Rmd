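---
title: "Evaluating the robustness of transcriptomic subtype signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating the robustness of transcriptomic subtype signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question this package asks

Transcriptomic subtyping systems for solid tumors — pancreatic ductal
adenocarcinoma (PDAC) is the motivating case — come with published gene
signatures: the two-class basal-like/classical split (50 tumor genes, plus
48 stroma genes for a normal/activated stroma split), a three-class scheme
(62 genes), a four-class scheme (613 genes) and a five-class scheme (403
genes). A signature is only useful if it recovers the same patient
subgroups in cohorts other than its discovery dataset, and if it
outperforms an arbitrary gene list of the same size. `sigrobust` provides
the machinery to test exactly that, on data where the truth is known:

1. **Clustering concordance.** Cluster samples on the signature genes only
   and compare the partition with reference labels via the Rand index and
   the Hubert–Arabie adjusted Rand index (ARI).
2. **Cross-cohort classification.** Train one random-forest classifier per
   (signature × labeled cohort) pair — four signatures by four discovery
   cohorts gives the sixteen-model grid — score each by stratified 5-fold
   cross-validation, and predict labels on external cohorts.
3. **Null models.** Repeat the classification with (a) fresh size-matched
   random signatures and (b) label permutations; repeat the clustering
   with random signatures and summarize real-vs-random against
   random-vs-random ARI distributions by the strictly standardized mean
   difference,
   \(\beta = (\mu_1 - \mu_2)/\sqrt{\sigma_1^2 + \sigma_2^2}\).
4. **Compositional follow-up.** Single-sample gene-set enrichment (ssGSEA)
   with per-subtype association (Welch t-test / one-way ANOVA, Bonferroni),
   and non-negative least-squares deconvolution of bulk profiles against a
   cell-type basis — the tool for asking whether "subtypes" merely track
   tissue composition (e.g. acinar contamination).
5. **Survival separation.** Kaplan–Meier estimates and pairwise two-group
   log-rank tests between predicted subtypes, reported as
   \(-\log_{10}(p)\) matrices without multiplicity correction (a
   `bonferroni` flag is available).

## The synthetic generator and its two reference regimes

Real multi-cohort collections cannot distinguish "the signature captures
biology" from "the signature captures sample composition" because the truth
is unknown. The generator (`simulation_config()`, `simulate_cohorts()`)
plants all of the relevant structure explicitly:

* **Subtype signal.** Gene \(i\) in class \(c\)'s signature block has mean
  \(\delta \cdot \sigma_{noise}\) in class-\(c\) samples and 0 elsewhere.
  Data are generated directly on a z-score-like Gaussian scale: the
  evaluation pipeline z-scores everything anyway, so a count model would
  add realism only upstream of the first transformation. This is a
  documented simplification — negative-binomial RNA-seq noise and
  platform-specific array artifacts are deliberately not modeled.
* **Batch effects.** Per-cohort, per-gene additive shifts drawn
  \(N(0, \sigma_{batch}^2)\), matching the additive model that
  `remove_batch_effect()` later fits.
* **Contamination.** A single "normal tissue" profile is drawn once per
  simulation from \(N(0,1)\) gene-wise; each sample is mixed as
  \((1-\varphi)\,\mathrm{tumor} + \varphi\,\mathrm{normal}\) with
  \(\varphi \sim U(\mathrm{lo}, \mathrm{hi})\). Because the same profile is
  shared by all samples, \(\varphi\) acts as a purity-correlated global
  signal on every gene — the mechanism by which acinar contamination can
  masquerade as a subtype.
* **Survival.** Exponential event times with hazard
  \(\lambda_0 \cdot \mathrm{HR}(c)\) per month and independent exponential
  censoring calibrated so the marginal censoring probability equals
  `censor_rate` (for event rate \(\lambda\) and target rate \(q\), the
  censoring rate is \(q\lambda/(1-q)\)). Ties are avoided by continuous
  times.

`scenario_config()` freezes two regimes used across tests and the
acceptance script. Both share one realistic backdrop — a 5000-gene
background and tumor purity varying as \(\varphi \sim U(0, 0.8)\), one
cohort of 150 samples, two balanced classes, 25 signature genes per class,
unit noise — and differ only in where the labels come from:

* **signal**: \(\delta = 3\); labels are the true planted subtypes,
  independent of purity.
* **confounded**: \(\delta = 0\); labels are quantile bins of \(\varphi\).

Two aspects of the backdrop matter and were chosen to mirror the data
regime the evaluation targets, not a convenient toy scale. First, the
universe must be large relative to the signature: with ~5000 candidate
genes a size-50 random signature usually contains no planted gene, which is
what makes "random signature" a genuine null — at a few hundred background
genes, random draws hit several planted genes and partially inherit the
signal, which says something about small universes, not about signatures.
Real expression matrices have 15–20k genes. Second, purity must vary
substantially (tumor cellularity in public cohorts ranges from highly pure
microdissected samples down to heavily contaminated resections): the shared
purity gradient is the dominant structure a random gene set can latch onto,
and it is exactly what makes the random-vs-random ARI distribution sit well
above the real-vs-random one in the signal regime — signature-derived
clusters track subtype, random-gene clusters track purity, and the SSMD
between the two ARI distributions is large. With a structure-free
background both distributions would degenerate to ~0 and the SSMD would be
uninformative rather than large.

What passing these scenarios shows — and does not show — about real data:
the pipeline detects a real signature when one exists and refuses to
prefer it over random genes when labels are composition-driven. It does
not certify any particular published signature, and the synthetic data
lack correlated co-expression modules, count noise and platform effects,
so absolute accuracies and SSMD magnitudes are not transferable to real
cohorts; only the contrasts between settings are.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `effect_size` | 3 | per-gene SD units | a clearly detectable but not trivial per-gene shift; single genes are informative yet the signature as a whole is far stronger |
| `noise_sd` | 1 | expression SD | the z-score-like scale unit |
| `batch_shift_sd` | 0.5 | SD units | mild cohort offsets, comparable to noise, removable by an additive model |
| `contamination_range` | (0, 0.3) generic; (0, 0.8) in scenarios | mixing fraction | purity spread; at 0.8 the global gradient dominates background structure |
| `survival_base_hazard` | 0.03 | events/month | median survival ~23 months at HR 1, the scale reported for PDAC subtypes |
| `class_hazard_ratios` | 1→2 across classes | — | a mild prognostic gradient; scenario survival uses 2.5 for clearer separation |
| `censor_rate` | 0.3 | probability | typical administrative censoring in public cohorts |
| `w` (ssGSEA) | 0.25 | exponent | the common reference weighting; `w = 0` gives the rank-only regime |
| `ntree`, `mtry` | 100, \(\lfloor\sqrt{p}\rfloor\) | — | frozen reference defaults of the canonical random-forest implementation (Gini splits, bootstrap resampling), recorded in the run manifest because "defaults" drift across versions |
| `n_reps` | 1000 | — | the reference battery size; tests and the acceptance script use 100 with correspondingly widened tolerance bands |

## Numerical and procedural choices

* **Preprocessing order.** For cross-cohort classification the order is
  intersect → merge → batch-correct → z-score, so z-scores are computed on
  batch-clean values. z-scoring uses the \(n-1\) SD and drops constant
  genes with a logged count. Batch correction fits the additive
  sum-to-zero model per gene (via `limma::removeBatchEffect`) and is
  idempotent; it is validated against a hand least-squares oracle in the
  tests.
* **Clustering.** Samples are the clustered units, genes the features.
  The metric is Pearson correlation distance (\(1-r\)) with average
  linkage — the conventional partner for a correlation metric; complete
  and Ward linkage are available as sensitivity flags. Clustering is
  deterministic and invariant to sample order up to cluster renaming.
* **Rank tests.** Wilcoxon rank-sum p-values are exact for combined
  \(n \le 25\) without ties, normal-approximated with tie and continuity
  correction otherwise; Kruskal–Wallis is tie-corrected. The Bonferroni
  family is the set of genes actually tested in that run (after overlap
  filtering), because signature overlap varies by dataset.
* **ARI conventions.** `adjusted_rand_index()` returns 1 for identical
  partitions including the degenerate all-singleton and single-cluster
  cases where the general formula is 0/0.
* **ssGSEA dialect.** Ranks (descending by expression, ties broken stably
  by input gene order) serve as weights via \(|\mathrm{rank}|^w\); the raw
  score is the sum over positions of the in-set minus out-of-set
  cumulative masses, and the term × sample matrix is normalized by its
  overall range. Weight, rank-vs-value weighting and normalization are
  exposed as arguments since dialects differ between implementations.
* **Random-signature pool.** The pool is the shared gene universe
  *including* the real signature's genes — the conservative null. Matched
  size is the signature's size after overlap filtering, not its nominal
  published size. Pairwise ARIs among random clusterings are subsampled
  to at most 10,000 seeded pairs when the replicate count makes the full
  pair set impractical.
* **SSMD.** Variances use the \(n-1\) denominator; both-degenerate input
  (zero total variance) is an error, not a number. Reporting layers show
  \(|\beta|\).
* **Deconvolution.** Sum-to-one NNLS against a user-supplied basis. This
  is a linear, open substitute for service-based deconvolution tools: the
  pipeline contract (bulk + basis → fractions) is the same, absolute
  fraction values are not comparable across methods. Rank-deficient bases
  are rejected; an all-zero NNLS fit falls back to uniform fractions.
* **Survival.** The log-rank statistic uses the standard aggregated risk
  set for tied event times and is cross-checked against an independent
  reference implementation to \(10^{-6}\). Pairs with zero pooled events
  yield flagged missing cells rather than numbers.
* **Seeding.** Every stochastic operation takes an explicit seed;
  batteries derive per-replicate seeds from the master seed via a seeded
  integer draw, so results are reproducible bit for bit and independent
  of evaluation order.

## Registry fixtures

The five packaged signatures carry the published sizes and class schemes
(50, 48, 62, 613, 403 genes; k = 2, 2, 3, 4, 5). Their gene lists are
synthetic stand-ins (filenames `*_synthetic.tsv`): the original
supplementary lists are not redistributed with this package. Sizes and
schemes are what the pipeline's structural checks rely on; a checksum file
guards the fixtures against silent drift, and `registry_verify()` checks
it. Gene symbols are matched case-sensitively after whitespace trimming;
alias resolution is out of scope.

## Problem sizes used in the shipped analyses

The module tests run the batteries at 100 replicates on single cohorts of
100–150 samples with 5050-gene universes (scenarios) or a few hundred
genes (unit fixtures); the sixteen-model grid uses four cohorts of 100
samples over a shared universe. These sizes were chosen so the full suite
and the acceptance analyses are comfortably reproducible on a laptop while
keeping every Monte-Carlo band meaningful at 100 replicates; the
1000-replicate reference settings are one argument away.

## Known limitations

* No count-scale model, no correlated background co-expression, no
  platform-specific artifacts: absolute performance numbers do not
  transfer to real cohorts.
* The deconvolution stand-in is linear and basis-dependent; it does not
  reproduce the output of proprietary deconvolution services.
* Consensus clustering, empirical-Bayes batch correction (ComBat),
  quantile normalization, Cox covariate adjustment and continuous
  molecular-gradient scoring are out of scope.
* The packaged signature gene lists are synthetic stand-ins with correct
  sizes and schemes, suitable for structural and pipeline checks, not for
  biological reuse.
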