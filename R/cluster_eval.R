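# Signature-restricted hierarchical clustering of samples, partition
# concordance (Rand index / adjusted Rand index), and per-gene
# subtype-association screening.

#' Correlation distance between two profiles
#'
#' `1 - Pearson correlation`, in `[0, 2]`.
#'
#' @param x,y numeric vectors of equal length >= 2, both non-constant.
#' @return The correlation distance.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("vectors must have equal length >= 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant vectors", call. = FALSE)
  1 - stats::cor(x, y)
}

#' Hierarchical clustering of samples on signature genes
#'
#' Samples are the clustered units; genes are features. The matrix (assumed
#' z-scored) is restricted to the signature genes, samples are clustered
#' agglomeratively on Pearson correlation distance, and the tree is cut to
#' exactly `k` clusters. Average linkage is the default partner for the
#' correlation metric; `linkage` switches to complete or Ward for
#' sensitivity runs.
#'
#' @param m an `ExpressionMatrix` (z-scored).
#' @param signature a `GeneSignature`, or a character vector of genes, or
#'   `NULL` to cluster on all genes.
#' @param k number of clusters (>= 2; defaults to the signature scheme's k).
#' @param linkage `"average"`, `"complete"` or `"ward.D2"`.
#' @return A list of class `ClusteringResult`: `assignments` (a
#'   `SubtypeLabelSet` with cluster names `C1..Ck`), `k`, `hclust` (the
#'   merge history) and `overlap` (number of signature genes present).
#' @export
hcluster <- function(m, signature = NULL, k = NULL,
                     linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (inherits(signature, "GeneSignature")) {
    if (is.null(k) && !is.null(signature$scheme)) k <- signature$scheme$k
    gene_set <- signature$genes
  } else gene_set <- signature
  if (is.null(k)) stop("`k` is required when the signature carries no scheme",
                       call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (!is.null(gene_set)) m <- restrict_genes(m, gene_set)
  if (ncol(m$values) < k)
    stop("need at least k samples to cut k clusters", call. = FALSE)
  if (nrow(m$values) < 2)
    stop("need >= 2 genes to compute correlation between samples", call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(m$values))
  hc <- stats::hclust(d, method = linkage)
  cut <- stats::cutree(hc, k = k)
  assign <- stats::setNames(paste0("C", cut), samples(m))
  structure(list(assignments = subtype_labels(assign,
                                              subtype_scheme(paste0("C", seq_len(k))),
                                              "cluster"),
                 k = as.integer(k), hclust = hc,
                 overlap = nrow(m$values)),
            class = "ClusteringResult")
}

as_partition <- function(x) {
  if (inherits(x, "ClusteringResult")) x <- x$assignments
  if (inherits(x, "SubtypeLabelSet")) x <- x$labels
  stats::setNames(as.character(x), names(x))
}

check_same_samples <- function(a, b) {
  pa <- as_partition(a); pb <- as_partition(b)
  if (!is.null(names(pa)) && !is.null(names(pb))) {
    if (!setequal(names(pa), names(pb)))
      stop("partitions cover different sample sets", call. = FALSE)
    pb <- pb[names(pa)]
  } else if (length(pa) != length(pb)) {
    stop("partitions have different lengths", call. = FALSE)
  }
  list(a = pa, b = pb)
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on which the partitions agree (co-clustered in
#' both or separated in both); in `[0, 1]`, invariant under class renaming.
#'
#' @param a,b partitions of the same samples: `SubtypeLabelSet`s,
#'   `ClusteringResult`s, or label vectors (matched by name when named).
#' @return The Rand index.
#' @export
rand_index <- function(a, b) {
  p <- check_same_samples(a, b)
  n <- length(p$a)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  tab <- table(p$a, p$b)
  sum_nij <- sum(choose(tab, 2))
  sum_ai <- sum(choose(rowSums(tab), 2))
  sum_bj <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_nij - sum_ai - sum_bj) / total
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected Rand index under the permutation model:
#' 0 expected for independent partitions, 1 iff the partitions are
#' identical up to renaming.
#'
#' @inheritParams rand_index
#' @return The adjusted Rand index (<= 1, may be negative).
#' @export
adjusted_rand_index <- function(a, b) {
  p <- check_same_samples(a, b)
  n <- length(p$a)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  tab <- table(p$a, p$b)
  index <- sum(choose(tab, 2))
  sum_ai <- sum(choose(rowSums(tab), 2))
  sum_bj <- sum(choose(colSums(tab), 2))
  expected <- sum_ai * sum_bj / choose(n, 2)
  max_index <- (sum_ai + sum_bj) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (index - expected) / (max_index - expected)
}

wilcox_p <- function(values, grp) {
  # exact p for combined n <= 25 without ties, normal approximation with
  # tie and continuity correction otherwise
  x <- values[grp]; y <- values[!grp]
  ties <- anyDuplicated(values) > 0
  exact <- !ties && length(values) <= 25
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                      exact = exact, correct = TRUE))$p.value
}

#' Per-gene association of expression with sample groups
#'
#' For each signature gene present in the matrix, tests whether its
#' expression differs between groups: two-sided Wilcoxon rank-sum for two
#' groups, Kruskal-Wallis (tie-corrected) for more. P-values are
#' Bonferroni-adjusted over the genes actually tested.
#'
#' @param m an `ExpressionMatrix`.
#' @param groups a `SubtypeLabelSet` covering the matrix samples; every
#'   group must have >= 2 samples.
#' @param genes a `GeneSignature` or character vector; `NULL` tests all
#'   matrix genes.
#' @return Named numeric vector of Bonferroni-adjusted p-values (one per
#'   tested gene), with the `-log10` values in the `"neglog10"` attribute.
#' @export
gene_association <- function(m, groups, genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(groups, "SubtypeLabelSet"))
  if (inherits(genes, "GeneSignature")) genes <- genes$genes
  if (!is.null(genes)) m <- restrict_genes(m, genes)
  labs <- groups$labels[samples(m)]
  if (anyNA(labs)) stop("groups must label every sample in the matrix",
                        call. = FALSE)
  counts <- table(labs)
  if (any(counts < 2)) stop("every group needs >= 2 samples", call. = FALSE)
  g <- factor(labs)
  n_tests <- nrow(m$values)
  p <- apply(m$values, 1, function(v) {
    if (length(unique(v)) == 1) return(1)  # all ties, no signal
    if (nlevels(g) == 2) wilcox_p(v, g == levels(g)[1])
    else stats::kruskal.test(v, g)$p.value
  })
  adj <- pmin(p * n_tests, 1)
  attr(adj, "neglog10") <- -log10(adj)
  adj
}

#' One-vs-rest per-gene association for multi-class schemes
#'
#' For each class of a k >= 3 scheme, a two-sided Wilcoxon rank-sum test of
#' each gene's expression in that class against all other samples.
#' Bonferroni correction is applied over all (gene, class) tests performed.
#'
#' @inheritParams gene_association
#' @return A genes x classes matrix of Bonferroni-adjusted p-values.
#' @export
pairwise_subtype_association <- function(m, groups, genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(groups, "SubtypeLabelSet"))
  if (inherits(genes, "GeneSignature")) genes <- genes$genes
  if (!is.null(genes)) m <- restrict_genes(m, genes)
  labs <- groups$labels[samples(m)]
  if (anyNA(labs)) stop("groups must label every sample in the matrix",
                        call. = FALSE)
  if (any(table(labs) < 2)) stop("every group needs >= 2 samples", call. = FALSE)
  classes <- groups$scheme$classes
  n_tests <- nrow(m$values) * length(classes)
  p <- sapply(classes, function(cl) {
    apply(m$values, 1, function(v) {
      if (length(unique(v)) == 1) return(1)
      wilcox_p(v, labs == cl)
    })
  })
  p <- matrix(pmin(1, p * n_tests), nrow(m$values), length(classes),
              dimnames = list(genes(m), classes))
  p
}
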