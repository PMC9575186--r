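# Null models for signature robustness: size-matched random signatures,
# shuffled labels, random-signature clustering ARIs, and the SSMD summary
# of the resulting replicate-statistic distributions.

#' Draw a size-matched random signature
#'
#' Uniform sample without replacement from the gene universe; the matched
#' size is the real signature's size after overlap filtering with the
#' dataset. Real signature genes are not excluded from the pool (the
#' conservative null).
#'
#' @param universe character vector of candidate genes.
#' @param size number of genes to draw (<= `length(universe)`).
#' @param seed integer seed.
#' @param name signature name.
#' @return A scheme-less `GeneSignature`.
#' @export
sample_random_signature <- function(universe, size, seed = 1L,
                                    name = "random") {
  if (size > length(universe))
    stop("requested size exceeds the gene universe", call. = FALSE)
  withr::with_seed(as.integer(seed),
    gene_signature(name, sample(universe, size)))
}

#' Shuffle subtype labels across samples
#'
#' A uniform permutation of the label vector over the samples; class
#' frequencies are preserved exactly.
#'
#' @param labels a `SubtypeLabelSet`.
#' @param seed integer seed.
#' @return A `SubtypeLabelSet` with permuted assignments.
#' @export
shuffle_labels <- function(labels, seed = 1L) {
  stopifnot(inherits(labels, "SubtypeLabelSet"))
  if (length(labels$labels) < 2) stop("need >= 2 samples", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    shuffled <- stats::setNames(sample(unname(labels$labels)),
                                names(labels$labels))
    subtype_labels(shuffled, labels$scheme, labels$origin)
  })
}

#' Classification null battery: real vs random signatures vs shuffled labels
#'
#' Repeats mean 5-fold CV accuracy under three settings: (a) the real
#' signature with a fresh CV fold seed each replicate, (b) a fresh
#' size-matched random signature each replicate, (c) the real signature
#' with freshly shuffled labels each replicate.
#'
#' @param m preprocessed `ExpressionMatrix` (the feature source).
#' @param labels truth `SubtypeLabelSet` for the cohort.
#' @param signature the real `GeneSignature` under evaluation.
#' @param n_reps replicates per setting (the reference battery uses 1000;
#'   scaled-down runs use 100).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param folds CV folds.
#' @return A list of class `ClassificationNull`: `real`, `random_signature`,
#'   `shuffled_labels` (each a `NullDistribution` of CV accuracies) and
#'   `summary` (median and maximum per setting).
#' @export
classification_null <- function(m, labels, signature, n_reps = 1000,
                                seed = 1L, folds = 5) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(labels, "SubtypeLabelSet"),
            inherits(signature, "GeneSignature"))
  universe <- genes(m)
  sig_genes <- intersect(signature$genes, universe)
  if (length(sig_genes) == 0)
    stop("signature has no overlap with the matrix genes", call. = FALSE)
  rep_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1, 3 * n_reps))
  X_real <- feature_matrix(m, sig_genes)
  acc_real <- acc_rand <- acc_shuf <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    s <- rep_seeds[(i - 1) * 3 + 1:3]
    acc_real[i] <- cv_accuracy(X_real, labels, folds = folds, seed = s[1])
    rand_sig <- sample_random_signature(universe, length(sig_genes), seed = s[2])
    acc_rand[i] <- cv_accuracy(feature_matrix(m, rand_sig$genes), labels,
                               folds = folds, seed = s[2])
    acc_shuf[i] <- cv_accuracy(X_real, shuffle_labels(labels, seed = s[3]),
                               folds = folds, seed = s[3])
  }
  dists <- list(
    real = null_distribution("real", "cv_accuracy", acc_real, seed),
    random_signature = null_distribution("random_signature", "cv_accuracy",
                                         acc_rand, seed),
    shuffled_labels = null_distribution("shuffled_labels", "cv_accuracy",
                                        acc_shuf, seed))
  summary <- data.frame(
    setting = names(dists),
    median = vapply(dists, function(d) stats::median(d$values), numeric(1)),
    max = vapply(dists, function(d) max(d$values), numeric(1)),
    row.names = NULL)
  structure(c(dists, list(summary = summary)), class = "ClassificationNull")
}

#' Clustering null battery: real-vs-random and random-vs-random ARIs
#'
#' Clusters the samples once on the real signature and `n_reps` times on
#' fresh size-matched random signatures. Returns list A — ARI between the
#' real-signature clustering and each random-signature clustering — and
#' list B — pairwise ARIs among the random-signature clusterings (all
#' unordered pairs, subsampled to at most `max_pairs` with a seeded draw
#' when the pair count is larger). `|SSMD|` of A versus B summarizes how
#' much signature-derived clusters differ from random-gene clusters.
#'
#' @param m a z-scored `ExpressionMatrix`.
#' @param signature the real `GeneSignature`.
#' @param k number of clusters (defaults to the signature scheme's k).
#' @param n_reps number of random signatures.
#' @param seed master seed.
#' @param max_pairs cap on the number of random-random pairs evaluated.
#' @param linkage linkage method passed to [hcluster()].
#' @return A list of class `ClusteringNull`: `real_vs_random` and
#'   `random_vs_random` (`NullDistribution`s of ARIs), `ssmd` (signed) and
#'   `ssmd_abs`.
#' @export
clustering_null <- function(m, signature, k = NULL, n_reps = 1000, seed = 1L,
                            max_pairs = 10000, linkage = "average") {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(signature, "GeneSignature"))
  universe <- genes(m)
  sig_genes <- intersect(signature$genes, universe)
  if (is.null(k) && !is.null(signature$scheme)) k <- signature$scheme$k
  real <- hcluster(m, sig_genes, k = k, linkage = linkage)
  rep_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1, n_reps + 1))
  rand_parts <- lapply(seq_len(n_reps), function(i) {
    rs <- sample_random_signature(universe, length(sig_genes),
                                  seed = rep_seeds[i])
    hcluster(m, rs$genes, k = k, linkage = linkage)$assignments
  })
  list_a <- vapply(rand_parts, function(p) adjusted_rand_index(real, p),
                   numeric(1))
  pairs <- utils::combn(n_reps, 2)
  if (ncol(pairs) > max_pairs) {
    keep <- withr::with_seed(rep_seeds[n_reps + 1],
                             sample.int(ncol(pairs), max_pairs))
    pairs <- pairs[, keep, drop = FALSE]
  }
  list_b <- vapply(seq_len(ncol(pairs)), function(j)
    adjusted_rand_index(rand_parts[[pairs[1, j]]], rand_parts[[pairs[2, j]]]),
    numeric(1))
  # SSMD needs a variance in each group; with a single random-random pair
  # the summary is undefined and reported as NA
  beta <- if (length(list_a) >= 2 && length(list_b) >= 2)
    ssmd(list_a, list_b) else NA_real_
  structure(list(real_vs_random = null_distribution("real_vs_random", "ari",
                                                    list_a, seed),
                 random_vs_random = null_distribution("random_vs_random", "ari",
                                                      list_b, seed),
                 real_clustering = real,
                 ssmd = beta, ssmd_abs = abs(beta)),
            class = "ClusteringNull")
}

#' Strictly standardized mean difference of two groups
#'
#' `beta = (mu1 - mu2) / sqrt(sigma1^2 + sigma2^2)` with the two groups
#' treated as independent with unequal variances; variances use the n - 1
#' denominator. Reporting layers usually show `|beta|`.
#'
#' @param g1,g2 numeric vectors of replicate statistics, or lists with
#'   elements `mean` and `var` (precomputed group summaries).
#' @return The signed SSMD.
#' @export
ssmd <- function(g1, g2) {
  summ <- function(g) {
    if (is.list(g)) list(mean = g$mean, var = g$var)
    else list(mean = mean(g), var = stats::var(g))
  }
  s1 <- summ(g1); s2 <- summ(g2)
  denom <- s1$var + s2$var
  if (denom == 0)
    stop("SSMD undefined: both group variances are zero", call. = FALSE)
  (s1$mean - s2$mean) / sqrt(denom)
}
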