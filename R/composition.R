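# Single-sample gene-set enrichment scoring, subtype association of
# enrichment profiles, and linear (NNLS) bulk deconvolution against a
# cell-type reference basis.

#' Single-sample GSEA running-sum score
#'
#' Genes are ranked by expression, descending (ties broken stably by input
#' gene order). Walking down the ranking, the in-set cumulative mass
#' accumulates `rank value ^ w` (the rank value of the gene at position
#' `i` is `N - i + 1`, so the top gene carries the largest weight),
#' normalized by the total in-set mass; the out-of-set cumulative mass
#' accumulates `1 / (N - m)` per out-of-set gene. The raw score is the sum
#' over all positions of (in-set cumulative minus out-of-set cumulative).
#' With `w = 0` the score depends on ranks only.
#'
#' @param expr named numeric expression vector over genes.
#' @param gene_set character vector; its intersection with the genes must
#'   be non-empty and a proper subset.
#' @param w rank-weighting exponent (default 0.25).
#' @return The raw (unnormalized) enrichment score.
#' @export
ssgsea_score <- function(expr, gene_set, w = 0.25) {
  if (is.null(names(expr))) stop("`expr` must be named by gene", call. = FALSE)
  n <- length(expr)
  in_set <- names(expr) %in% gene_set
  m <- sum(in_set)
  if (m == 0) stop("gene set has no overlap with the expression vector",
                   call. = FALSE)
  if (m == n) stop("gene set covers all genes; score undefined", call. = FALSE)
  ord <- order(expr, decreasing = TRUE)  # stable: ties keep input order
  in_ord <- in_set[ord]
  rank_val <- seq(n, 1)
  weights <- rank_val^w
  p_in <- cumsum(ifelse(in_ord, weights, 0)) / sum(weights[in_ord])
  p_out <- cumsum(!in_ord) / (n - m)
  sum(p_in - p_out)
}

#' Enrichment-score matrix over a gene-set library
#'
#' Scores every sample of an expression matrix against every gene set and
#' (optionally) normalizes the full matrix by dividing by the range
#' (max - min) of all raw scores.
#'
#' @param m an `ExpressionMatrix`.
#' @param gene_sets named list of gene vectors (or `GeneSignature`s), e.g.
#'   from [read_signature()] on a GMT library.
#' @param w rank-weighting exponent.
#' @param normalize divide by the overall score range (default `TRUE`).
#' @return A terms x samples numeric matrix of enrichment scores of class
#'   `EnrichmentProfile`.
#' @export
ssgsea_matrix <- function(m, gene_sets, w = 0.25, normalize = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"), length(gene_sets) >= 1)
  sets <- lapply(gene_sets, function(s)
    if (inherits(s, "GeneSignature")) s$genes else as.character(s))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named", call. = FALSE)
  scores <- vapply(seq_len(ncol(m$values)), function(j) {
    v <- m$values[, j]
    names(v) <- genes(m)
    vapply(sets, function(s) ssgsea_score(v, s, w), numeric(1))
  }, numeric(length(sets)))
  scores <- matrix(scores, nrow = length(sets),
                   dimnames = list(names(sets), samples(m)))
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  class(scores) <- c("EnrichmentProfile", class(scores))
  scores
}

#' Subtype association of enrichment scores
#'
#' Per term, tests whether the enrichment score differs across the groups:
#' two-sided Welch t-test for two groups, one-way ANOVA for more, with
#' Bonferroni correction over terms. A term's associated class is the one
#' with the highest mean enrichment score (ties report all tied classes);
#' the direction is the sign of that class's mean score.
#'
#' @param profile a terms x samples matrix from [ssgsea_matrix()].
#' @param groups a `SubtypeLabelSet` covering the profile's samples; every
#'   group needs >= 2 samples.
#' @return A data.frame with one row per term: `term`, `p_adjusted`,
#'   `significant` (adjusted p < 0.05), `associated_class` (comma-joined if
#'   tied), `direction` (`"up"`/`"down"`), and per-class mean scores in the
#'   `"class_means"` attribute.
#' @export
enrichment_association <- function(profile, groups) {
  stopifnot(is.matrix(profile), inherits(groups, "SubtypeLabelSet"))
  labs <- groups$labels[colnames(profile)]
  if (anyNA(labs)) stop("groups must label every profile sample", call. = FALSE)
  if (any(table(labs) < 2)) stop("every group needs >= 2 samples", call. = FALSE)
  g <- factor(labs, levels = groups$scheme$classes)
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  n_terms <- nrow(profile)
  p <- apply(profile, 1, function(v) {
    if (stats::var(v) == 0) return(1)
    if (nlevels(g) == 2) {
      stats::t.test(v[g == levels(g)[1]], v[g == levels(g)[2]],
                    var.equal = FALSE)$p.value
    } else {
      stats::anova(stats::aov(v ~ g))[["Pr(>F)"]][1]
    }
  })
  p_adj <- pmin(1, p * n_terms)
  class_means <- t(apply(profile, 1, function(v) tapply(v, g, mean)))
  assoc <- apply(class_means, 1, function(mu) {
    top <- which(mu == max(mu))
    paste(colnames(class_means)[top], collapse = ",")
  })
  direction <- apply(class_means, 1,
                     function(mu) if (max(mu) >= 0) "up" else "down")
  out <- data.frame(term = rownames(profile), p_adjusted = unname(p_adj),
                    significant = unname(p_adj) < 0.05,
                    associated_class = unname(assoc),
                    direction = unname(direction),
                    stringsAsFactors = FALSE)
  attr(out, "class_means") <- class_means
  out
}

#' Non-negative least-squares deconvolution of bulk profiles
#'
#' Linear stand-in for reference-based cell-type deconvolution: per sample,
#' fractions are fitted by non-negative least squares against the basis on
#' the shared genes and renormalized to sum to one. The pipeline contract
#' (bulk + basis -> fractions) matches proprietary deconvolution services;
#' absolute values will differ from them.
#'
#' @param bulk an `ExpressionMatrix`.
#' @param basis a [cell_type_basis()]; the shared genes must be at least as
#'   many as cell types and the basis full column rank on them.
#' @return A cell types x samples matrix of fractions in `[0, 1]`, columns
#'   summing to 1.
#' @export
nnls_deconvolve <- function(bulk, basis) {
  stopifnot(inherits(bulk, "ExpressionMatrix"), inherits(basis, "CellTypeBasis"))
  shared <- intersect(genes(bulk), rownames(basis$basis))
  n_types <- length(basis$cell_types)
  if (length(shared) < n_types)
    stop("need at least as many shared genes as cell types", call. = FALSE)
  B <- basis$basis[shared, , drop = FALSE]
  if (qr(B)$rank < n_types)
    stop("basis is rank-deficient on the shared genes", call. = FALSE)
  Y <- bulk$values[shared, , drop = FALSE]
  fr <- vapply(seq_len(ncol(Y)), function(j) {
    f <- pracma::lsqnonneg(B, Y[, j])$x
    if (sum(f) == 0) rep(1 / n_types, n_types) else f / sum(f)
  }, numeric(n_types))
  fr <- matrix(fr, nrow = n_types,
               dimnames = list(basis$cell_types, colnames(Y)))
  fr
}
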