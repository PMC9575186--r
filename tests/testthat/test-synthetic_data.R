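test_that("identical configurations reproduce identical outputs bitwise", {
  cfg <- simulation_config(n_cohorts = 2, samples_per_cohort = 30,
                           n_background_genes = 40, seed = 7)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a$cohorts[[1]]$expression$values,
                   b$cohorts[[1]]$expression$values)
  expect_identical(a$cohorts[[2]]$survival, b$cohorts[[2]]$survival)
  expect_identical(a$signature$genes, b$signature$genes)
})

test_that("the null configuration plants no class differences", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 200,
                           effect_size = 0, batch_shift_sd = 0,
                           contamination_range = c(0, 0), noise_sd = 1,
                           n_background_genes = 50, seed = 3)
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts[[1]]
  cls <- co$labels$labels
  for (g in sim$signature$genes[c(1, 30)]) {
    mu <- tapply(co$expression$values[g, names(cls)], cls, mean)
    expect_lt(abs(diff(mu)), 4 * 1 / sqrt(min(table(cls))))
  }
})

test_that("planted genes carry the configured effect size", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 100, k = 2,
                           effect_size = 3, batch_shift_sd = 0,
                           contamination_range = c(0, 0),
                           n_background_genes = 50, seed = 1)
  sim <- simulate_cohorts(cfg)
  co <- sim$cohorts[[1]]
  cls <- co$labels$labels
  g <- sim$signature$genes[1]  # class1 block
  tt <- t.test(co$expression$values[g, names(cls)[cls == "class1"]],
               co$expression$values[g, names(cls)[cls == "class2"]])
  expect_gt(abs(tt$statistic), 5)
})

test_that("class counts follow the multinomial sampling model", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 200, k = 2,
                           class_proportions = c(0.5, 0.5),
                           n_background_genes = 20, seed = 5)
  sim <- simulate_cohorts(cfg)
  counts <- table(sim$cohorts[[1]]$labels$labels)
  band <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(class_proportions = c(0.6, 0.5)),
               "sum to 1")
  expect_error(simulation_config(contamination_range = c(0.5, 0.2)),
               "lo <= hi")
  expect_error(simulation_config(contamination_range = c(-0.1, 0.5)),
               "lo <= hi")
  expect_error(simulation_config(n_background_genes = 0), ">= 1")
  expect_error(simulation_config(k = 3, class_hazard_ratios = c(1, 2)),
               "length k")
  expect_error(simulate_mixtures(cell_type_basis(40), 10, noise_sd = -1),
               "noise_sd")
})

test_that("the Kruskal-Wallis screen recovers planted signal", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 100, k = 3,
                           n_signature_genes_per_class = 20,
                           effect_size = 3, batch_shift_sd = 0,
                           contamination_range = c(0, 0),
                           n_background_genes = 200, seed = 2)
  sim <- simulate_cohorts(cfg)
  m <- zscore_genes(sim$cohorts[[1]]$expression)
  p_adj <- gene_association(m, sim$cohorts[[1]]$labels, sim$signature)
  expect_gte(mean(p_adj < 0.05), 0.95)
})

test_that("survival generation honours hazard ratios and censoring", {
  cfg <- simulation_config(n_cohorts = 1, samples_per_cohort = 400, k = 2,
                           survival_base_hazard = 0.05,
                           class_hazard_ratios = c(1, 4), censor_rate = 0.3,
                           n_background_genes = 20, seed = 9)
  sim <- simulate_cohorts(cfg)
  surv <- sim$cohorts[[1]]$survival
  expect_true(all(surv$time >= 0))
  # marginal censoring rate calibrated to the configured value
  expect_lt(abs(mean(surv$event == 0) - 0.3), 0.07)
  med <- tapply(surv$time, surv$group, median)
  expect_gt(med["class1"], med["class2"])  # HR 4 shortens class2 survival
})

test_that("Dirichlet mixtures follow the requested concentration", {
  basis <- cell_type_basis(n_genes = 60, cell_types = c("a", "b", "c"),
                           seed = 1)
  conc <- simulate_mixtures(basis, 20, dirichlet_alpha = c(100, 0.01, 0.01),
                            noise_sd = 0, seed = 2)
  expect_true(all(conc$fractions["a", ] > 0.95))
  expect_equal(conc$expression$values[, 1],
               (basis$basis %*% conc$fractions[, 1])[, 1],
               tolerance = 1e-12, ignore_attr = TRUE)

  flat <- simulate_mixtures(basis, 500, dirichlet_alpha = c(1, 1, 1),
                            noise_sd = 0, seed = 3)
  expect_true(all(abs(rowMeans(flat$fractions) - 1 / 3) < 0.06))
})

test_that("a battery shares one gene universe with disjoint planted blocks", {
  configs <- lapply(2:4, function(k)
    simulation_config(samples_per_cohort = 30, k = k,
                      n_signature_genes_per_class = 5,
                      n_background_genes = 50, seed = k))
  bat <- simulate_battery(configs, seed = 1)
  g1 <- genes(bat$cohorts[[1]]$expression)
  for (co in bat$cohorts[-1])
    expect_identical(genes(co$expression), g1)
  expect_length(intersect(bat$signatures$sig1$genes,
                          bat$signatures$sig2$genes), 0)
  expect_true(all(bat$signatures$sig3$genes %in% g1))
  expect_equal(bat$cohorts[[2]]$labels$scheme$k, 3)
})
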