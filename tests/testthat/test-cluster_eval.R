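test_that("correlation distance matches the Pearson formula", {
  x <- c(1, 2, 3)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(correlation_distance(x, -x), 2)
  expect_equal(correlation_distance(x, c(1, 2, 4)), 1 - cor(x, c(1, 2, 4)))
  expect_equal(correlation_distance(x, c(1, 2, 4)), 0.01801949,
               tolerance = 1e-6)
  expect_error(correlation_distance(x, c(2, 2, 2)), "constant")
  expect_error(correlation_distance(x, c(1, 2)), "equal length")
})

test_that("hclustering separates well-separated blobs and handles edge cuts", {
  blobs <- make_blobs(n_per_class = 20, n_genes = 40, delta = 5, seed = 2)
  z <- zscore_genes(blobs$expression)
  cl <- hcluster(z, k = 2)
  expect_equal(adjusted_rand_index(cl, blobs$labels), 1)
  expect_equal(cl$k, 2L)
  expect_equal(length(unique(cl$assignments$labels)), 2)

  # degenerate cut: as many clusters as samples
  small <- tiny_em(matrix(rnorm(40), 4, 10))
  singles <- hcluster(small, k = 10)
  expect_equal(length(unique(singles$assignments$labels)), 10)

  # duplicated samples co-cluster (zero-distance pairs)
  v <- matrix(rnorm(20), 4, 5)
  dup <- tiny_em(cbind(v, v), sample_names = sprintf("s%d", 1:10))
  dcl <- hcluster(dup, k = 2)
  a <- dcl$assignments$labels
  expect_identical(unname(a[1:5]), unname(a[6:10]))
})

test_that("hclustering is invariant to sample order up to renaming", {
  blobs <- make_blobs(n_per_class = 15, delta = 3, seed = 4)
  z <- zscore_genes(blobs$expression)
  cl1 <- hcluster(z, k = 2)
  perm <- withr::with_seed(9, sample(ncol(z$values)))
  z2 <- expression_matrix(z$values[, perm], "shuffled", "synthetic")
  cl2 <- hcluster(z2, k = 2)
  expect_equal(adjusted_rand_index(cl1, cl2), 1)
})

test_that("hcluster validates signature overlap and k", {
  m <- tiny_em(matrix(rnorm(40), 4, 10))
  expect_error(hcluster(m, c("nope1", "nope2"), k = 2), "no overlap")
  expect_error(hcluster(m, k = 1), ">= 2")
  expect_error(hcluster(tiny_em(matrix(rnorm(8), 4, 2)), k = 3),
               "at least k samples")
})

test_that("RI and ARI match the worked example and are renaming-invariant", {
  a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
  expect_equal(rand_index(a, b), 1 / 3)
  expect_equal(adjusted_rand_index(a, b), -0.5)
  expect_equal(rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, a), 1)
  relabeled <- c("x", "x", "y", "y")
  expect_equal(rand_index(relabeled, b), rand_index(a, b))
  expect_equal(adjusted_rand_index(relabeled, b), adjusted_rand_index(a, b))
  expect_error(rand_index(setNames(a, paste0("s", 1:4)),
                          setNames(b, paste0("t", 1:4))),
               "different sample sets")
})

test_that("RI and ARI agree with independent oracles on all small partitions", {
  skip_if_not_installed("mclust")
  for (n in 2:5) {
    parts <- all_partitions(n)
    idx <- expand.grid(i = seq_along(parts), j = seq_along(parts))
    mine_ri <- oracle_ri <- mine_ari <- oracle_ari <- numeric(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      a <- parts[[idx$i[r]]]; b <- parts[[idx$j[r]]]
      mine_ri[r] <- rand_index(a, b)
      oracle_ri[r] <- oracle_rand(a, b)
      mine_ari[r] <- adjusted_rand_index(a, b)
      ref <- mclust::adjustedRandIndex(a, b)
      # the reference returns NaN for the degenerate identical trivial
      # partitions where max index equals its expectation; the convention
      # here (as in the definition) is ARI = 1 for identical partitions
      oracle_ari[r] <- if (is.nan(ref)) 1 else ref
    }
    expect_equal(mine_ri, oracle_ri)
    expect_equal(mine_ari, oracle_ari)
  }
})

test_that("ARI of independent random partitions is centred at zero", {
  aris <- withr::with_seed(11, vapply(1:1000, function(i) {
    adjusted_rand_index(sample(1:3, 200, replace = TRUE),
                        sample(1:3, 200, replace = TRUE))
  }, numeric(1)))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("gene association applies the right test and Bonferroni family", {
  # all-ties gene -> adjusted p = 1
  m <- tiny_em(rbind(rep(1, 6), c(1, 2, 3, 10, 11, 12)))
  labs <- subtype_labels(setNames(rep(c("A", "B"), each = 3), samples(m)),
                         subtype_scheme(c("A", "B")), "truth")
  p <- suppressMessages(gene_association(m, labs))
  expect_equal(unname(p["g1"]), 1)
  # exact two-sided rank-sum p for 3 vs 3 with no overlap is 0.1;
  # Bonferroni family = 2 genes tested here
  expect_equal(unname(p["g2"]), 0.2)

  single <- gene_association(tiny_em(matrix(c(1, 2, 3, 10, 11, 12), 1, 6,
                                            dimnames = list("g2", samples(m)))),
                             labs)
  expect_equal(unname(single["g2"]), 0.1)
  expect_equal(unname(attr(single, "neglog10")["g2"]), 1)

  tiny <- subtype_labels(setNames(c("A", "A", "A", "A", "A", "B"), samples(m)),
                         subtype_scheme(c("A", "B")), "truth")
  expect_error(gene_association(m, tiny), ">= 2 samples")
})

test_that("one-vs-rest screening localizes the shifted class", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 90, k = 3,
                           class_proportions = rep(1 / 3, 3),
                           n_signature_genes_per_class = 10, effect_size = 3,
                           contamination_range = c(0, 0), batch_shift_sd = 0,
                           n_background_genes = 30, seed = 6)
  sim <- simulate_cohorts(cfg)
  m <- zscore_genes(sim$cohorts[[1]]$expression)
  labs <- sim$cohorts[[1]]$labels
  p <- pairwise_subtype_association(m, labs, sim$signature)
  expect_equal(dim(p), c(30L, 3L))
  # class1's planted block should be most significant one-vs-rest in class1
  block1 <- sim$signature$genes[1:10]
  med <- apply(p[block1, ], 2, median)
  expect_equal(names(which.min(med)), "class1")

  # k = 2 reduces to the two-group test up to the multiplicity constant
  blobs <- make_blobs(n_per_class = 10, delta = 2, seed = 3)
  z <- zscore_genes(blobs$expression)
  p2 <- pairwise_subtype_association(z, blobs$labels)
  g2 <- gene_association(z, blobs$labels)
  # one-vs-rest for either class is the same two-group comparison, so the
  # adjusted p-values differ only by the multiplicity constant (2 classes)
  expect_equal(unname(p2[, "A"]), unname(pmin(1, 2 * g2)), tolerance = 1e-12)
  expect_equal(unname(p2[, "A"]), unname(p2[, "B"]), tolerance = 1e-12)
})
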