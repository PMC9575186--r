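# sigrobust

Are published tumor-subtype gene signatures actually capturing subtypes —
or just the composition of the samples they were derived from?

`sigrobust` is an R package for benchmarking the robustness of
transcriptomic subtype signatures, built around the evaluation strategy
used for pancreatic ductal adenocarcinoma (PDAC), where two-, three-,
four- and five-class subtyping systems (gene signatures of 50+48, 62, 613
and 403 genes) coexist and disagree. It is aimed at computational
biologists who want to stress-test a signature before trusting its
subtype calls.

## What it computes

* **Clustering concordance** — agglomerative hierarchical clustering of
  samples restricted to signature genes (Pearson correlation distance,
  average linkage), compared with reference labels by the Rand index and
  the adjusted Rand index (ARI).
* **Cross-cohort classification** — one random-forest classifier per
  (signature × labeled training cohort); four signatures by four
  discovery cohorts is the sixteen-model grid. Models are scored by mean
  accuracy from stratified 5-fold cross-validation and can predict labels
  on external cohorts, after shared-gene intersection, additive batch
  correction and z-scoring.
* **Null models** — repeat every evaluation with size-matched random gene
  sets and with permuted labels. Real-vs-random and random-vs-random ARI
  distributions are summarized by the strictly standardized mean
  difference, β = (μ₁ − μ₂) / √(σ₁² + σ₂²).
* **Compositional follow-up** — single-sample GSEA (weighted running-sum
  scores, per-subtype association by Welch t-test / ANOVA with Bonferroni
  correction) and non-negative least-squares deconvolution of bulk
  profiles against a cell-type basis, for asking whether predicted
  "subtypes" track tissue contamination (e.g. acinar content).
* **Survival separation** — Kaplan–Meier estimates and pairwise two-group
  log-rank tests between predicted subtypes, reported as −log₁₀(p)
  matrices.
* **A synthetic multi-cohort generator** — planted subtype signal of
  known effect size, per-cohort batch shifts, per-sample normal-tissue
  contamination, cell-type mixtures and subtype-dependent exponential
  survival, so every stage can be validated against ground truth.

## Worked example

Simulate the "signal" reference scenario — one 150-sample cohort, two
balanced subtypes carried by a planted 50-gene signature (effect size 3
SD) on a 5050-gene universe, with tumor purity varying as U(0, 0.8) —
then evaluate the planted signature against its nulls:

```r
library(sigrobust)

sim    <- simulate_cohorts(scenario_config("signal", seed = 7))
cohort <- sim$cohorts$cohort1
z      <- zscore_genes(cohort$expression)

cl <- hcluster(z, sim$signature)
adjusted_rand_index(cl, cohort$labels)
#> clustering ARI vs truth: 1

nulls <- classification_null(z, cohort$labels, sim$signature,
                             n_reps = 50, seed = 8)
nulls$summary
#>            setting median   max
#> 1             real  1.000 1.000
#> 2 random_signature  0.566 0.960
#> 3  shuffled_labels  0.520 0.594

cl_null <- clustering_null(z, sim$signature, n_reps = 50, seed = 9)
cl_null$ssmd_abs
#> clustering |SSMD| real-vs-random against random-vs-random: 4.16

surv <- pairwise_logrank(cohort$labels, cohort$survival)
surv["class1", "class2"]
#> survival -log10(p), class1 vs class2: 8.53
```

Reading the numbers: the planted signature recovers the true subtypes
perfectly in clustering (ARI 1) and classification (median CV accuracy
1.000), while size-matched random signatures hover near chance (median
0.566) and permuted labels at the majority-class rate (0.520) — though
note the *maximum* random-signature accuracy over 50 draws reaches 0.960,
the kind of occasional random-gene success that motivates running the
nulls at all. The clustering |SSMD| of 4.16 says signature-derived
clusters stand far apart from random-gene clusters (which all track the
shared purity gradient instead), and the subtypes separate survival
(−log₁₀ p ≈ 8.5, planted hazard ratio 2.5). In the complementary
"confounded" scenario (`scenario_config("confounded")`: no planted
signal, labels driven by tumor purity) the same battery shows real and
random signatures performing indistinguishably — the failure mode this
package exists to expose.

A full configuration-driven run (`run_pipeline()`) accepts a YAML or list
config, executes simulate → preprocess → cluster → classify → robustness
→ composition → survival, and writes per-stage TSV/JSON outputs plus a
manifest under an output directory.

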