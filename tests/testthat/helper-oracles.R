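# Shared fixtures and independent oracles used across the suite.

tiny_em <- function(values, gene_names = NULL, sample_names = NULL,
                    cohort_id = "test") {
  if (is.null(gene_names))
    gene_names <- if (!is.null(rownames(values))) rownames(values)
                  else paste0("g", seq_len(nrow(values)))
  if (is.null(sample_names))
    sample_names <- if (!is.null(colnames(values))) colnames(values)
                    else paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(gene_names, sample_names)
  expression_matrix(values, cohort_id, "synthetic")
}

# pair-counting Rand index, computed directly over all sample pairs
# (independent of the contingency-table implementation under test)
oracle_rand <- function(a, b) {
  same_a <- outer(a, a, "==")[upper.tri(diag(length(a)))]
  same_b <- outer(b, b, "==")[upper.tri(diag(length(b)))]
  mean(same_a == same_b)
}

# all set partitions of n elements, as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, max_block) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(max_block + 1))
      grow(c(prefix, b), max(max_block, b))
  }
  grow(integer(0), 0L)
  out
}

# literal position-by-position running sum, independent of the vectorized
# implementation under test
oracle_ssgsea <- function(expr, gene_set, w) {
  ord <- order(expr, decreasing = TRUE)
  nms <- names(expr)[ord]
  n <- length(expr)
  m <- sum(nms %in% gene_set)
  rank_val <- n:1
  total_in <- sum((rank_val^w)[nms %in% gene_set])
  p_in <- p_out <- 0
  score <- 0
  for (i in seq_len(n)) {
    if (nms[i] %in% gene_set) p_in <- p_in + rank_val[i]^w / total_in
    else p_out <- p_out + 1 / (n - m)
    score <- score + (p_in - p_out)
  }
  score
}

# quick labeled two-blob dataset: class B is shifted on the first half of
# the genes only, so the separation is a profile pattern (visible to the
# correlation metric), not a uniform offset (which correlation ignores)
make_blobs <- function(n_per_class = 50, n_genes = 20, delta = 5, seed = 1) {
  withr::with_seed(seed, {
    shift <- rep(c(delta, 0), each = ceiling(n_genes / 2))[seq_len(n_genes)]
    vals <- cbind(matrix(rnorm(n_genes * n_per_class), n_genes),
                  matrix(rnorm(n_genes * n_per_class), n_genes) + shift)
    ids <- sprintf("s%03d", seq_len(2 * n_per_class))
    dimnames(vals) <- list(paste0("g", seq_len(n_genes)), ids)
    labs <- subtype_labels(
      stats::setNames(rep(c("A", "B"), each = n_per_class), ids),
      subtype_scheme(c("A", "B")), "truth")
    list(expression = expression_matrix(vals, "blobs", "synthetic"),
         labels = labs)
  })
}

random_survival_fixture <- function(seed, n = 40, rate2_mult = 1) {
  withr::with_seed(seed, {
    t1 <- rexp(n, 0.05); t2 <- rexp(n, 0.05 * rate2_mult)
    c1 <- rexp(n, 0.02); c2 <- rexp(n, 0.02)
    list(g1 = survival_table(sprintf("a%d", 1:n), pmin(t1, c1),
                             as.numeric(t1 <= c1), "g1"),
         g2 = survival_table(sprintf("b%d", 1:n), pmin(t2, c2),
                             as.numeric(t2 <= c2), "g2"))
  })
}
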